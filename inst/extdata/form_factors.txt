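# 4-Gaussian independent-atom scattering factors
# f(s) = sum_i a_i * exp(-b_i * s^2) + c,  s = sin(theta)/lambda  [1/A]
# element a1 a2 a3 a4 b1 b2 b3 b4 c
H 0.493002 0.322912 0.140191 0.040810 10.510900 26.125700 3.142360 57.799700 0.003038
C 2.310000 1.020000 1.588600 0.865000 20.843900 10.207500 0.568700 51.651200 0.215600
N 12.212600 3.132200 2.012500 1.166300 0.005700 9.893300 28.997500 0.582600 -11.529000
O 3.048500 2.286800 1.546300 0.867000 13.277100 5.701100 0.323900 32.908900 0.250800
F 3.539200 2.641200 1.517000 1.024300 10.282500 4.294400 0.261500 26.147600 0.277600
Na 4.762600 3.173600 1.267400 1.112800 3.285000 8.842200 0.313600 129.424000 0.676000
Mg 5.420400 2.173500 1.226900 2.307300 2.827500 79.261100 0.380800 7.193700 0.858400
P 6.434500 4.179100 1.780000 1.490800 1.906700 27.157000 0.526000 68.164500 1.114900
S 6.905300 5.203400 1.437900 1.586300 1.467900 22.215100 0.253600 56.172000 0.866900
Cl 11.460400 7.196400 6.255600 1.645500 0.010400 1.166200 18.519400 47.778400 -9.557400
K 8.218600 7.439800 1.051900 0.865900 12.794900 0.774800 213.187000 41.684100 1.422800
Ca 8.626600 7.387300 1.589900 1.021100 10.442100 0.659900 85.748400 178.437000 1.375100
V 10.297100 7.351100 2.070300 2.057100 6.865700 0.438500 26.893800 102.478000 1.219900
Cr 10.640600 7.353700 3.324000 1.492200 6.103800 0.392000 20.262600 98.739900 1.183200
Mn 11.281900 7.357300 3.019300 2.244100 5.340900 0.343200 17.867400 83.754300 1.089600
Fe 11.769500 7.357300 3.522200 2.304500 4.761100 0.307200 15.353500 76.880500 1.036900
Co 12.284100 7.340900 4.003400 2.348800 4.279100 0.278400 13.535900 71.169200 1.011800
Ni 12.837600 7.292000 4.443800 2.380000 3.878500 0.256500 12.176300 66.342100 1.034100
Cu 13.338000 7.167600 5.615800 1.673500 3.582800 0.247000 11.396600 64.812600 1.191000
Zn 14.074300 7.031800 5.165200 2.410000 3.265500 0.233300 10.316300 58.709700 1.304100
Se 17.000600 5.819600 3.973100 4.354300 2.409800 0.272600 15.237200 43.816300 2.840900
Br 17.178900 5.235800 5.637700 3.985100 2.172300 16.579600 0.260900 41.432800 2.955700
Mo 3.702500 17.235600 12.887600 3.742900 0.277200 1.095800 11.004000 61.658400 4.387500
I 20.147200 18.994900 7.513800 2.273500 4.347000 0.381400 27.766000 66.877600 4.071200
W 29.081800 15.430000 14.432700 5.119820 1.720290 9.225900 0.321703 57.056000 9.887500
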