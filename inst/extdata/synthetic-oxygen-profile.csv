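depth_um,conc_umol_per_L,analyte
0,248.3331360076591,oxygen
50,249.90081344083382,oxygen
100,256.4280606769729,oxygen
150,260.02867950364043,oxygen
200,264.30349992842923,oxygen
250,265.6897335012774,oxygen
300,268.0925022526571,oxygen
350,269.6820340810001,oxygen
400,269.6883985644343,oxygen
450,266.5934406707051,oxygen
500,270.241978712029,oxygen
550,270.3186388601254,oxygen
600,270.26160313897753,oxygen
650,268.48675803687354,oxygen
700,270.53699048618984,oxygen
750,267.9823211573701,oxygen
800,267.1265714085797,oxygen
850,267.87254062864673,oxygen
900,267.3090268145289,oxygen
950,267.9629769114422,oxygen
1000,266.6806878432977,oxygen
1050,271.37197580722307,oxygen
1100,267.8012187776506,oxygen
1150,267.3506851145824,oxygen
1200,265.8615356189652,oxygen
1250,269.7963268693766,oxygen
1300,266.6016459573359,oxygen
1350,265.4288118685105,oxygen
1400,262.7170023576648,oxygen
1450,261.81268048526266,oxygen
1500,264.2659846670626,oxygen
1550,262.2758963522549,oxygen
1600,261.7808514362895,oxygen
1650,263.64013399650025,oxygen
1700,262.0362839790356,oxygen
1750,265.3499095412599,oxygen
1800,260.5042692390186,oxygen
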