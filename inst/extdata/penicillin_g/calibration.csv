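concentration,area,replicate
4,424.5091,1
4,425.363705,2
4,425.054778,3
4,425.521412,4
4,426.142216,5
4,425.096894,6
4,425.046357,7
4,425.534316,8
4,424.385292,9
4,424.98512,10
20,1168.652545,1
20,1169.294889,2
20,1168.266308,3
20,1168.708665,4
20,1168.481188,5
20,1168.993532,6
20,1169.53884,7
20,1168.109342,8
20,1169.228202,9
20,1169.12049,10
100,4889.162549,1
100,4888.498728,2
100,4888.649861,3
100,4888.502098,4
100,4888.925074,5
100,4889.48508,6
100,4889.224258,7
100,4888.740114,8
100,4888.850526,9
100,4889.151634,10
500,23489.123059,1
500,23488.86614,2
500,23489.100108,3
500,23489.593727,4
500,23489.286479,5
500,23488.831495,6
500,23488.833339,7
500,23489.368528,8
500,23489.518558,9
500,23488.980719,10
5000,232739.561273,1
5000,232738.962929,2
5000,232739.183774,3
5000,232738.862153,4
5000,232739.341078,5
5000,232738.782641,6
5000,232739.307137,7
5000,232739.383306,8
5000,232738.961074,9
5000,232738.917841,10
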