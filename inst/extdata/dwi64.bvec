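 0.00000000000  0.70254703663 -0.12314082788  0.45850164433  0.60612306443  0.36456866810 -0.12472884181  0.85740239831  0.05339128653  0.76018539806 -0.21618922397  0.86899367947  0.91971137153 -0.83769798376 -0.10612276522 -0.21699335765  0.43283620523  0.21618627415 -0.85625701643 -0.95765209623  0.97612564000 -0.38364328089 -0.70805805150 -0.68981510822  0.46384537146  0.70571378273 -0.33350424474  0.07120263295 -0.71852238231  0.50370028517 -0.55376336695  0.15330522774  0.43388538645  0.63254171947 -0.55508381927  0.90324355128 -0.82930609945 -0.63890907704 -0.42875144303 -0.79726799946  0.04345539830  0.30968237787 -0.35477595083  0.78498442750 -0.53324643628 -0.60043604641  0.11720971184 -0.65643901501  0.92325802364 -0.15872646618  0.24194583229  0.29739276049 -0.79422187535  0.95328740504  0.29491770345 -0.19109617240  0.48035390723  0.33926604884  0.02299934124 -0.99253774107  0.02213380910 -0.42871388988  0.17245094772  0.65481794064  0.50275284140
 0.00000000000 -0.22708268738  0.98418543723  0.67642553445  0.66307171002  0.92244863101  0.50385029711 -0.07421952329  0.18679233700  0.38144931227 -0.45679886375 -0.27859541289  0.39043590706  0.54362456943  0.46875254172 -0.87191155026 -0.89218365685  0.62112595219 -0.04857016870  0.17599156393 -0.02298755664 -0.65050718180  0.34485927193 -0.72319058122 -0.13137395537  0.45043032291  0.84564866101  0.71948733338 -0.16247576388  0.84517916165  0.62725680012 -0.89655822297 -0.43840557630 -0.76950254974 -0.76966630507  0.21643724176  0.43399559306  0.52863402493  0.42832340157 -0.53677350979  0.98427961578 -0.93784743476 -0.15482023759 -0.55457370622 -0.39417798046  0.11755533736  0.06793852809 -0.10516798505  0.27868796839 -0.36289232830 -0.69408552293 -0.19494942959 -0.56905889607 -0.29287918379  0.85351197379 -0.97112062405  0.40562733515 -0.69305109657 -0.75888063805 -0.08962438818 -0.90139240891 -0.12528025874 -0.18759642933 -0.70777078815 -0.77719839307
 0.00000000000 -0.67443392146 -0.12733955261  0.57638939832 -0.43926158282  0.12719359023  0.85473831909  0.50926671767 -0.98094749776 -0.52594161533  0.86290035202 -0.40894324906  0.04111928457 -0.05229163919 -0.87693158988 -0.43895800627  0.12907804574  0.75330342253  0.51426147097 -0.22788030193 -0.21598682178  0.65548321066 -0.61621901810 -0.03391901694 -0.87612119894  0.54688260263 -0.41671724330 -0.69084597572 -0.67625972249 -0.17876858626 -0.54762673431 -0.41554886593  0.78711118788 -0.08807269196 -0.31542944128  0.37054825252 -0.35199320819  0.55887499403  0.79543149533 -0.27611218051  0.17118781008 -0.15664933436  0.92204377268 -0.27612941341  0.74851316482 -0.79098501682  0.99078062146  0.74701239246 -0.26443834455 -0.91821297475  0.67801733097  0.93464017991  0.21303423557 -0.07392500997 -0.42958219095  0.14285302392  0.77764168406 -0.63606503256 -0.65082348413 -0.08268193031  0.43243707016 -0.89471182925 -0.96698927106  0.26509239155 -0.37842071597
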