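# Reference values computed once with PyWavelets 1.9 (db5, symmetric
# extension) and SciPy 1.17 (welch: periodic Hamming, density scaling;
# shapiro). Frozen here so the suite runs self-contained.
pywt_x <- c(0.30471700000000002, -1.039984, 0.75045099999999998, 0.94056499999999998, -1.9510350000000001, -1.3021799999999999, 0.12784000000000001, -0.316243, -0.016801, -0.85304400000000002, 0.87939800000000001, 0.77779200000000004, 0.066031000000000006, 1.1272409999999999, 0.46750900000000001, -0.85929199999999994, 0.368751, -0.95888300000000004, 0.87844999999999995, -0.049925999999999998, -0.184862, -0.68093000000000004, 1.2225410000000001, -0.154529)
pywt_cA <- c(-1.5286659216247274, -0.33544951113671401, -0.075109252051098391, -0.2638000385977266, 0.61854271700614782, -0.93054573566812893, -0.95197293946168271, -0.54955865398791548, 0.20828514598370215, 0.75212004393116938, 0.92098456317254518, -0.54688329175497585, 0.27796255214115995, -0.42056205571993321, 0.37325573859070682, 0.33461458212291956)
pywt_cD <- c(0.29735650841917316, 1.1124004423292089, -1.8133615736504693, 1.0837583066030605, 0.030870630375823101, 1.0688006819172982, -0.78753392517381038, -0.1646358171365129, 1.2576753927564379, 0.98558765972164208, -0.010924892384532259, 1.2529668579429576, -0.17934854867427313, -1.3090421796049387, 0.16522002253112503, -1.3957900203603963)
welch_nd_density <- c(0.13207851031706069, 0.17642112187542142, 0.047921489682938974, 0.0035284373379879572, 8.0779547745439413e-31, 8.167992017041987e-05, 1.9866175143035493e-29, 6.3246887982458598e-05, 1.9811855763122636e-29, 0.002230559277024658, 0.033278812279819055, 0.12412890866578642, 0.18344237544036265, 0.12091034600893875, 0.033278812279818791, 0.0026767811200009268, 7.2526134057613961e-31, 6.3759638047115411e-05, 7.376832397414975e-31, 4.7608258205026257e-05, 8.6109299107742621e-31, 4.6924155577924445e-05, 5.6732345141467859e-31, 4.8176193061175466e-05, 5.7551878473733272e-31, 5.1456186338261827e-05, 8.6999134897093935e-31, 5.6746234871206578e-05, 2.58649049317329e-30, 6.3527216785840774e-05, 7.5869204605738257e-31, 6.8825451115703365e-05, 9.6557055814701253e-31, 5.8694907763732798e-05, 1.6678801216397518e-30, 7.3587768942100608e-06, 8.4569481462751046e-31, 0.0091112616724452079, 0.13311524911927544, 0.49243846313527045, 0.73376950176144862, 0.48804277168366755, 0.13311524911927466, 0.009715350116688103, 4.60627134008943e-31, 1.3620037720956475e-05, 4.5926975373794034e-31, 1.9458240213030164e-05, 8.1702070458726596e-31, 2.4700134352443742e-05, 7.5822142330217986e-31, 2.080329455321869e-05, 2.6021789744314339e-30, 1.6079105639110425e-05, 9.7301110426602785e-30, 1.2200286399483082e-05, 3.8835655975522015e-30, 9.2626128168060001e-06, 6.3405943183815294e-31, 7.0752778343254535e-06, 1.4425635097684646e-30, 5.4424021042871778e-06, 9.9253159721123078e-31, 4.2121367379163605e-06, 2.4222696043407465e-31, 3.2747869673324048e-06, 8.1013915315652969e-31, 2.5525214297500327e-06, 4.1649132858079248e-31, 1.9900866772179213e-06, 3.5595838376521936e-31, 1.5479521129125763e-06, 6.9696423807985834e-31, 1.1975421237084344e-06, 2.1813323291372882e-30, 9.1797914395480654e-07, 2.178034174107525e-30, 6.9386415067918311e-07, 6.4299578605798353e-31, 5.1375962061077387e-07, 1.4829876266202785e-30, 3.6915039101387915e-07, 1.2707141220847384e-30, 2.5373580552790018e-07, 1.5824361876314364e-30, 1.6295984653781343e-07, 1.6282361531916128e-29, 9.3722499258221508e-08, 1.7663959323560526e-29, 4.4239509149402527e-08, 1.502432351101558e-30, 1.4023957414111739e-08, 8.4542450617590732e-31, 3.9152168959563337e-09, 7.1994808315985223e-31, 1.5814178873892361e-08, 1.6619756649804933e-30, 5.0569560523857493e-08, 6.4000128234268702e-31, 9.7093297325571473e-08, 9.7104409371198992e-31, 8.8398653725989486e-08, 1.5501335088312917e-30, 1.66380199399371e-07, 6.5753070128611501e-31, 9.7810826743445988e-05, 0.0013311524911927537, 0.0048814206019140759, 0.0073376950176144628, 0.0049175150383845654, 0.0013311524911927158, 9.2818546641560865e-05, 2.1718935530726514e-30, 6.4419000100247053e-08, 3.4725342295849459e-30, 3.3808855796456707e-07, 7.7686511299597132e-31, 3.6243565941706498e-07, 1.4098907724311359e-30, 2.7655985115438666e-07, 5.5799240422853859e-30, 1.9254206626347958e-07, 9.5452981858464904e-30, 1.3057839939442919e-07, 3.5189473461814155e-30, 9.126662042739029e-08, 1.2137414709689875e-30, 7.235240250026793e-08, 4.2007283415577599e-31)
welch_ct_density <- c(1.3797052597134809e-31, 7.6694790943370011e-05, 4.1841652309979044e-31, 7.6365330127616085e-05, 8.0644158518299313e-31, 6.9714635118104867e-05, 1.9859562020088133e-29, 3.3276983034258038e-05, 1.9761769370538105e-29, 0.0020100244776886174, 0.033278812279819062, 0.12536816146673566, 0.18344237544036265, 0.11977211870970088, 0.033278812279818784, 0.0027904905795047706, 7.2610796737540277e-31, 4.7107044926109587e-05, 7.3055115950819808e-31, 2.4802830860189589e-05, 8.5737735419113555e-31, 2.5448028716555539e-05, 5.5417301475004406e-31, 2.8544511566338647e-05, 5.6190445528297139e-31, 3.329506161182196e-05, 8.9183367298419808e-31, 3.9609391022105631e-05, 2.5638227974624435e-30, 4.7068200347608929e-05, 7.568265318625402e-31, 5.2986498567710951e-05, 9.5593966990511602e-31, 4.4531035801554515e-05, 1.6713813180062654e-30, 2.4877188129818768e-06, 8.5246465071223402e-31, 0.0092205322759362184, 0.13311524911927544, 0.49159990935275916, 0.73376950176144862, 0.48887072001087617, 0.13311524911927466, 0.0095953364852888866, 4.6203821086189121e-31, 7.4656579889970391e-06, 4.5373365897752884e-31, 2.2154180600490331e-05, 8.2343750049817135e-31, 2.8443887215055975e-05, 7.5554919550434257e-31, 2.4318801033564644e-05, 2.6003218276993463e-30, 1.9153150971425002e-05, 9.7582399373301772e-30, 1.4846238964665814e-05, 3.9025867096239749e-30, 1.1540519225685926e-05, 6.3610921831400388e-31, 9.0473845119722551e-06, 1.4640564631192076e-30, 7.1626015287963129e-06, 9.8322402920944943e-31, 5.7246686314931458e-06, 2.5248296728301354e-31, 4.6153736485582049e-06, 8.2419492022153202e-31, 3.749938786529879e-06, 4.0590614511658494e-31, 3.0676027683703613e-06, 3.5840709230134617e-31, 2.5245082973117798e-06, 6.9129990101683398e-31, 2.0886854673470378e-06, 2.1520547548219873e-30, 1.7365887452550306e-06, 2.1422256337843825e-30, 1.4507161848045525e-06, 6.3963572613715082e-31, 1.2179691936313857e-06, 1.4701158231794371e-30, 1.0285202140058522e-06, 1.2803415014232999e-30, 8.7503435831654098e-07, 1.5792710313910804e-30, 7.5214516935046753e-07, 1.6250765587188139e-29, 6.5612091577086596e-07, 1.7692394560407444e-29, 5.8467853325102016e-07, 1.4794452164985887e-30, 5.3689759486464589e-07, 8.421505724522839e-31, 5.1310464662385451e-07, 7.2048801415581654e-31, 5.1421957882821861e-07, 1.6566376066457015e-30, 5.3843023131839077e-07, 6.4699409521638764e-31, 5.6590184755474907e-07, 9.6421583281250863e-31, 4.9476486078717908e-07, 1.5748372144762115e-30, 2.7107775022095295e-07, 6.3524633639280108e-31, 9.4628353991189229e-05, 0.0013311524911927546, 0.0049034332391471105, 0.0073376950176144628, 0.0048979318109984033, 0.0013311524911927164, 9.5368675854245696e-05, 2.1938069942789309e-30, 2.0602427366763513e-07, 3.4323510769595519e-30, 3.2900933570066669e-07, 7.8539423132111478e-31, 3.5083857944006947e-07, 1.4260960972489084e-30, 2.8012156544801834e-07, 5.6394516453269916e-30, 2.104484670666768e-07, 9.492338955483784e-30, 1.5910869363541129e-07, 3.5149442737988539e-30, 1.2659935849698627e-07, 1.2245730784483719e-30, 1.1098032314119315e-07, 4.3726132901435517e-31)
shapiro_x <- c(0.00123, 0.29874600000000001, -0.27413799999999999, -0.89059200000000005, -0.45467099999999999, -0.99164699999999995, 0.060144000000000003, 1.3402149999999999, -0.49220700000000001, -0.620475, 0.489842, 0.35688700000000001, 0.10541399999999999, -0.93046799999999996, -0.029252, 0.695303, -1.3442149999999999, -0.45761600000000002, -1.9012230000000001, -1.2895380000000001, -1.8417349999999999, -0.23509099999999999, -1.2674460000000001, 0.27126400000000001, 0.156751, -0.18693100000000001, -2.5167600000000001, -0.53869299999999998, -0.048501000000000002, 0.11330900000000001, -1.5301359999999999, -0.47775299999999998, -0.97851900000000003, -0.80883700000000003, 1.060899, -0.807535, -0.032522000000000002, 0.88439000000000001, -0.58360000000000001, -0.111702, 0.11046400000000001, 0.063782000000000005, -1.2250559999999999, 0.076139999999999999, 1.3588229999999999, -1.547145, 0.85938300000000001, 0.119354, -0.64146999999999998, 2.0004170000000001)
shapiro_W <- 0.989730584805
shapiro_p <- 0.939687537356
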