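spectrum_id,offset,exponent,n_peaks,r2,cf1,cf2,cf3
1,1.516278,0.986487,1,0.997403,11.773634,,
2,0.243848,0.651762,2,0.995497,6.455277,22.902313,
3,0.309422,1.965121,0,0.999391,,,
4,1.004555,0.965092,1,0.998098,6.715542,,
5,0.226958,1.749116,2,0.999014,10.952020,23.840709,
6,-0.070782,1.888669,0,0.999387,,,
7,0.380273,0.603682,1,0.996483,6.559213,,
8,1.973525,1.265057,2,0.998493,8.362212,24.306744,
9,0.731444,1.543433,0,0.999137,,,
10,1.339595,0.764057,1,0.997072,6.882949,,
11,1.028654,1.207085,2,0.998155,12.996935,23.084416,
12,0.059640,0.811465,0,0.996218,,,
13,-0.074138,1.490265,1,0.999283,8.487045,,
14,0.744657,1.832492,2,0.999081,14.239191,24.684765,
15,-0.351260,1.205478,0,0.998107,,,
16,1.738472,1.737355,1,0.999247,12.173368,,
17,-0.968675,1.689753,2,0.998727,14.669876,26.136041,
18,0.071918,1.834393,0,0.999266,,,
19,0.709500,0.950653,1,0.997726,6.692717,,
20,-0.553239,0.680820,2,0.995481,5.176338,21.287969,
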