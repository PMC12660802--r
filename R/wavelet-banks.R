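# Two-channel perfect-reconstruction filter banks for the wavelet families used
# in the stationary-wavelet denoiser.  These are the standard published
# Daubechies, symlet, coiflet and (reverse) biorthogonal spline filter
# coefficients; each bank satisfies conv(rec_lo, dec_lo) + conv(rec_hi, dec_hi)
# = 2 * delta, which the transform's inverse relies on.

.wavelet_banks <- list(
  `db4` = list(
    dec_lo = c(-0.010597401785069032, 0.032883011666885197, 0.030841381835560764, -0.18703481171909309,
      -0.027983769416859854, 0.63088076792985892, 0.71484657055291567, 0.23037781330889651),
    dec_hi = c(-0.23037781330889651, 0.71484657055291567, -0.63088076792985892, -0.027983769416859854,
      0.18703481171909309, 0.030841381835560764, -0.032883011666885197, -0.010597401785069032),
    rec_lo = c(0.23037781330889651, 0.71484657055291567, 0.63088076792985892, -0.027983769416859854,
      -0.18703481171909309, 0.030841381835560764, 0.032883011666885197, -0.010597401785069032),
    rec_hi = c(-0.010597401785069032, -0.032883011666885197, 0.030841381835560764, 0.18703481171909309,
      -0.027983769416859854, -0.63088076792985892, 0.71484657055291567, -0.23037781330889651)),
  `db5` = list(
    dec_lo = c(0.0033357252854737712, -0.012580751999081999, -0.0062414902127982744, 0.077571493840045719,
      -0.032244869584638375, -0.24229488706638203, 0.13842814590132074, 0.72430852843777294,
      0.60382926979718965, 0.16010239797419293),
    dec_hi = c(-0.16010239797419293, 0.60382926979718965, -0.72430852843777294, 0.13842814590132074,
      0.24229488706638203, -0.032244869584638375, -0.077571493840045719, -0.0062414902127982744,
      0.012580751999081999, 0.0033357252854737712),
    rec_lo = c(0.16010239797419293, 0.60382926979718965, 0.72430852843777294, 0.13842814590132074,
      -0.24229488706638203, -0.032244869584638375, 0.077571493840045719, -0.0062414902127982744,
      -0.012580751999081999, 0.0033357252854737712),
    rec_hi = c(0.0033357252854737712, 0.012580751999081999, -0.0062414902127982744, -0.077571493840045719,
      -0.032244869584638375, 0.24229488706638203, 0.13842814590132074, -0.72430852843777294,
      0.60382926979718965, -0.16010239797419293)),
  `db6` = list(
    dec_lo = c(-0.0010773010853084796, 0.0047772575109455108, 0.00055384220116149613, -0.03158203931748603,
      0.027522865530305727, 0.097501605587323043, -0.12976686756726194, -0.22626469396543983,
      0.31525035170919763, 0.75113390802109536, 0.49462389039845306, 0.11154074335010947),
    dec_hi = c(-0.11154074335010947, 0.49462389039845306, -0.75113390802109536, 0.31525035170919763,
      0.22626469396543983, -0.12976686756726194, -0.097501605587323043, 0.027522865530305727,
      0.03158203931748603, 0.00055384220116149613, -0.0047772575109455108, -0.0010773010853084796),
    rec_lo = c(0.11154074335010947, 0.49462389039845306, 0.75113390802109536, 0.31525035170919763,
      -0.22626469396543983, -0.12976686756726194, 0.097501605587323043, 0.027522865530305727,
      -0.03158203931748603, 0.00055384220116149613, 0.0047772575109455108, -0.0010773010853084796),
    rec_hi = c(-0.0010773010853084796, -0.0047772575109455108, 0.00055384220116149613, 0.03158203931748603,
      0.027522865530305727, -0.097501605587323043, -0.12976686756726194, 0.22626469396543983,
      0.31525035170919763, -0.75113390802109536, 0.49462389039845306, -0.11154074335010947)),
  `sym4` = list(
    dec_lo = c(-0.075765714789273325, -0.02963552764599851, 0.49761866763201545, 0.80373875180591614,
      0.29785779560527736, -0.099219543576847216, -0.012603967262037833, 0.032223100604042702),
    dec_hi = c(-0.032223100604042702, -0.012603967262037833, 0.099219543576847216, 0.29785779560527736,
      -0.80373875180591614, 0.49761866763201545, 0.02963552764599851, -0.075765714789273325),
    rec_lo = c(0.032223100604042702, -0.012603967262037833, -0.099219543576847216, 0.29785779560527736,
      0.80373875180591614, 0.49761866763201545, -0.02963552764599851, -0.075765714789273325),
    rec_hi = c(-0.075765714789273325, 0.02963552764599851, 0.49761866763201545, -0.80373875180591614,
      0.29785779560527736, 0.099219543576847216, -0.012603967262037833, -0.032223100604042702)),
  `sym5` = list(
    dec_lo = c(0.027333068345077982, 0.029519490925774643, -0.039134249302383094, 0.1993975339773936,
      0.72340769040242059, 0.63397896345821192, 0.016602105764522319, -0.17532808990845047,
      -0.021101834024758855, 0.019538882735286728),
    dec_hi = c(-0.019538882735286728, -0.021101834024758855, 0.17532808990845047, 0.016602105764522319,
      -0.63397896345821192, 0.72340769040242059, -0.1993975339773936, -0.039134249302383094,
      -0.029519490925774643, 0.027333068345077982),
    rec_lo = c(0.019538882735286728, -0.021101834024758855, -0.17532808990845047, 0.016602105764522319,
      0.63397896345821192, 0.72340769040242059, 0.1993975339773936, -0.039134249302383094,
      0.029519490925774643, 0.027333068345077982),
    rec_hi = c(0.027333068345077982, -0.029519490925774643, -0.039134249302383094, -0.1993975339773936,
      0.72340769040242059, -0.63397896345821192, 0.016602105764522319, 0.17532808990845047,
      -0.021101834024758855, -0.019538882735286728)),
  `coif3` = list(
    dec_lo = c(-3.4599773197272781e-05, -7.0983302506379004e-05, 0.00046621695982040288, 0.0011175187708306303,
      -0.0025745176881367972, -0.0090079761367306242, 0.015880544863669452, 0.034555027573297738,
      -0.082301927106299827, -0.071799821619154838, 0.42848347637737, 0.79377722262608719,
      0.40517690240911824, -0.061123390002972552, -0.065771911281469364, 0.023452696142077168,
      0.0077825964256727463, -0.0037935128643808019),
    dec_hi = c(0.0037935128643808019, 0.0077825964256727463, -0.023452696142077168, -0.065771911281469364,
      0.061123390002972552, 0.40517690240911824, -0.79377722262608719, 0.42848347637737,
      0.071799821619154838, -0.082301927106299827, -0.034555027573297738, 0.015880544863669452,
      0.0090079761367306242, -0.0025745176881367972, -0.0011175187708306303, 0.00046621695982040288,
      7.0983302506379004e-05, -3.4599773197272781e-05),
    rec_lo = c(-0.0037935128643808019, 0.0077825964256727463, 0.023452696142077168, -0.065771911281469364,
      -0.061123390002972552, 0.40517690240911824, 0.79377722262608719, 0.42848347637737,
      -0.071799821619154838, -0.082301927106299827, 0.034555027573297738, 0.015880544863669452,
      -0.0090079761367306242, -0.0025745176881367972, 0.0011175187708306303, 0.00046621695982040288,
      -7.0983302506379004e-05, -3.4599773197272781e-05),
    rec_hi = c(-3.4599773197272781e-05, 7.0983302506379004e-05, 0.00046621695982040288, -0.0011175187708306303,
      -0.0025745176881367972, 0.0090079761367306242, 0.015880544863669452, -0.034555027573297738,
      -0.082301927106299827, 0.071799821619154838, 0.42848347637737, -0.79377722262608719,
      0.40517690240911824, 0.061123390002972552, -0.065771911281469364, -0.023452696142077168,
      0.0077825964256727463, 0.0037935128643808019)),
  `coif4` = list(
    dec_lo = c(-1.7849909144933469e-06, -3.259647940030751e-06, 3.1229861599195265e-05, 6.2338854312787192e-05,
      -0.00025997433712225682, -0.00058902022463321654, 0.0012665610789256603, 0.0037514346971460866,
      -0.0056582838001308835, -0.015211728187697211, 0.025082253337949612, 0.039334422605589149,
      -0.096220424535952642, -0.066627472366817167, 0.43438603311435653, 0.78223893442428261,
      0.41530842700068227, -0.056077319603569258, -0.081266710249193727, 0.02668230466960483,
      0.016068947131575029, -0.0073461679362680507, -0.001629492425226786, 0.00089231390253700297),
    dec_hi = c(-0.00089231390253700297, -0.001629492425226786, 0.0073461679362680507, 0.016068947131575029,
      -0.02668230466960483, -0.081266710249193727, 0.056077319603569258, 0.41530842700068227,
      -0.78223893442428261, 0.43438603311435653, 0.066627472366817167, -0.096220424535952642,
      -0.039334422605589149, 0.025082253337949612, 0.015211728187697211, -0.0056582838001308835,
      -0.0037514346971460866, 0.0012665610789256603, 0.00058902022463321654, -0.00025997433712225682,
      -6.2338854312787192e-05, 3.1229861599195265e-05, 3.259647940030751e-06, -1.7849909144933469e-06),
    rec_lo = c(0.00089231390253700297, -0.001629492425226786, -0.0073461679362680507, 0.016068947131575029,
      0.02668230466960483, -0.081266710249193727, -0.056077319603569258, 0.41530842700068227,
      0.78223893442428261, 0.43438603311435653, -0.066627472366817167, -0.096220424535952642,
      0.039334422605589149, 0.025082253337949612, -0.015211728187697211, -0.0056582838001308835,
      0.0037514346971460866, 0.0012665610789256603, -0.00058902022463321654, -0.00025997433712225682,
      6.2338854312787192e-05, 3.1229861599195265e-05, -3.259647940030751e-06, -1.7849909144933469e-06),
    rec_hi = c(-1.7849909144933469e-06, 3.259647940030751e-06, 3.1229861599195265e-05, -6.2338854312787192e-05,
      -0.00025997433712225682, 0.00058902022463321654, 0.0012665610789256603, -0.0037514346971460866,
      -0.0056582838001308835, 0.015211728187697211, 0.025082253337949612, -0.039334422605589149,
      -0.096220424535952642, 0.066627472366817167, 0.43438603311435653, -0.78223893442428261,
      0.41530842700068227, 0.056077319603569258, -0.081266710249193727, -0.02668230466960483,
      0.016068947131575029, 0.0073461679362680507, -0.001629492425226786, -0.00089231390253700297)),
  `coif5` = list(
    dec_lo = c(-9.6040101127678941e-08, -1.6237995172048338e-07, 2.0612203985788783e-06, 3.7007277113394796e-06,
      -2.1270221672515614e-05, -4.1219861924265501e-05, 0.00014035632812373243, 0.00030185794166824478,
      -0.00063755892612588115, -0.0016616273039298788, 0.0024315754425382886, 0.0067615202206204169,
      -0.0091595073386761625, -0.019758391600965465, 0.032674799467057355, 0.041287530472117834,
      -0.10556315130733723, -0.06203775157498196, 0.43798230665916338, 0.77429362286032744,
      0.42157126673075435, -0.052046670253554764, -0.091921588060086087, 0.028169744270532353,
      0.023408322118927783, -0.010131584846900276, -0.0041593126275786402, 0.0021782943778456947,
      0.00035857774116175768, -0.000212081862067494),
    dec_hi = c(0.000212081862067494, 0.00035857774116175768, -0.0021782943778456947, -0.0041593126275786402,
      0.010131584846900276, 0.023408322118927783, -0.028169744270532353, -0.091921588060086087,
      0.052046670253554764, 0.42157126673075435, -0.77429362286032744, 0.43798230665916338,
      0.06203775157498196, -0.10556315130733723, -0.041287530472117834, 0.032674799467057355,
      0.019758391600965465, -0.0091595073386761625, -0.0067615202206204169, 0.0024315754425382886,
      0.0016616273039298788, -0.00063755892612588115, -0.00030185794166824478, 0.00014035632812373243,
      4.1219861924265501e-05, -2.1270221672515614e-05, -3.7007277113394796e-06, 2.0612203985788783e-06,
      1.6237995172048338e-07, -9.6040101127678941e-08),
    rec_lo = c(-0.000212081862067494, 0.00035857774116175768, 0.0021782943778456947, -0.0041593126275786402,
      -0.010131584846900276, 0.023408322118927783, 0.028169744270532353, -0.091921588060086087,
      -0.052046670253554764, 0.42157126673075435, 0.77429362286032744, 0.43798230665916338,
      -0.06203775157498196, -0.10556315130733723, 0.041287530472117834, 0.032674799467057355,
      -0.019758391600965465, -0.0091595073386761625, 0.0067615202206204169, 0.0024315754425382886,
      -0.0016616273039298788, -0.00063755892612588115, 0.00030185794166824478, 0.00014035632812373243,
      -4.1219861924265501e-05, -2.1270221672515614e-05, 3.7007277113394796e-06, 2.0612203985788783e-06,
      -1.6237995172048338e-07, -9.6040101127678941e-08),
    rec_hi = c(-9.6040101127678941e-08, 1.6237995172048338e-07, 2.0612203985788783e-06, -3.7007277113394796e-06,
      -2.1270221672515614e-05, 4.1219861924265501e-05, 0.00014035632812373243, -0.00030185794166824478,
      -0.00063755892612588115, 0.0016616273039298788, 0.0024315754425382886, -0.0067615202206204169,
      -0.0091595073386761625, 0.019758391600965465, 0.032674799467057355, -0.041287530472117834,
      -0.10556315130733723, 0.06203775157498196, 0.43798230665916338, -0.77429362286032744,
      0.42157126673075435, 0.052046670253554764, -0.091921588060086087, -0.028169744270532353,
      0.023408322118927783, 0.010131584846900276, -0.0041593126275786402, -0.0021782943778456947,
      0.00035857774116175768, 0.000212081862067494)),
  `bior3.5` = list(
    dec_lo = c(-0.013810679320049757, 0.041432037960149271, 0.052480581416189075, -0.26792717880896527,
      -0.07181553246425873, 0.96674755240348298, 0.96674755240348298, -0.07181553246425873,
      -0.26792717880896527, 0.052480581416189075, 0.041432037960149271, -0.013810679320049757),
    dec_hi = c(-0, 0, -0, 0,
      -0.17677669529663689, 0.5303300858899106, -0.5303300858899106, 0.17677669529663689,
      -0, 0, -0, 0),
    rec_lo = c(0, 0, 0, 0,
      0.17677669529663689, 0.5303300858899106, 0.5303300858899106, 0.17677669529663689,
      0, 0, 0, 0),
    rec_hi = c(-0.013810679320049757, -0.041432037960149271, 0.052480581416189075, 0.26792717880896527,
      -0.07181553246425873, -0.96674755240348298, 0.96674755240348298, 0.07181553246425873,
      -0.26792717880896527, -0.052480581416189075, 0.041432037960149271, 0.013810679320049757)),
  `rbio3.9` = list(
    dec_lo = c(0, 0, 0, 0,
      0, 0, 0, 0,
      0.17677669529663689, 0.5303300858899106, 0.5303300858899106, 0.17677669529663689,
      0, 0, 0, 0,
      0, 0, 0, 0),
    dec_hi = c(0.0006797443727836989, 0.0020392331183510968, -0.0050603192196119811, -0.020618912641105536,
      0.014112787930175844, 0.09913478249423216, -0.012300136269419315, -0.32019196836077857,
      -0.0020500227115698858, 0.94212570067820678, -0.94212570067820678, 0.0020500227115698858,
      0.32019196836077857, 0.012300136269419315, -0.09913478249423216, -0.014112787930175844,
      0.020618912641105536, 0.0050603192196119811, -0.0020392331183510968, -0.0006797443727836989),
    rec_lo = c(-0.0006797443727836989, 0.0020392331183510968, 0.0050603192196119811, -0.020618912641105536,
      -0.014112787930175844, 0.09913478249423216, 0.012300136269419315, -0.32019196836077857,
      0.0020500227115698858, 0.94212570067820678, 0.94212570067820678, 0.0020500227115698858,
      -0.32019196836077857, 0.012300136269419315, 0.09913478249423216, -0.014112787930175844,
      -0.020618912641105536, 0.0050603192196119811, 0.0020392331183510968, -0.0006797443727836989),
    rec_hi = c(0, -0, 0, -0,
      0, -0, 0, -0,
      0.17677669529663689, -0.5303300858899106, 0.5303300858899106, -0.17677669529663689,
      0, -0, 0, -0,
      0, -0, 0, -0)))
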