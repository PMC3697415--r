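##TITLE=Synthetic averaged pure-water NIR spectrum (not measured data)
##JCAMP-DX=4.24
##DATA TYPE=INFRARED SPECTRUM
##XUNITS=1/CM
##YUNITS=ABSORBANCE
$$ synthetic stand-in generated from the package default water band model
##XYPOINTS=(XY..XY)
11800.0, 0.000031; 11600.0, 0.000303; 11400.0, 0.002149; 11200.0, 0.010997; 11000.0, 0.040601; 10800.0, 0.108134; 10600.0, 0.207771; 10400.0, 0.288002; 10200.0, 0.288002; 10000.0, 0.207771; 9800.0, 0.108134; 9600.0, 0.040601; 9400.0, 0.010997; 9200.0, 0.002149; 9000.0, 0.000303; 8800.0, 0.000031; 8600.0, 0.000002; 8400.0, 0.000001; 8200.0, 0.000018; 8000.0, 0.000378; 7800.0, 0.004852; 7600.0, 0.037346; 7400.0, 0.172578; 7200.0, 0.478787; 7000.0, 0.797483; 6800.0, 0.797483; 6600.0, 0.478787; 6400.0, 0.172578; 6200.0, 0.037358; 6000.0, 0.005426; 5800.0, 0.013097; 5600.0, 0.123465; 5400.0, 0.524316; 5200.0, 0.974504; 5000.0, 0.792599; 4800.0, 0.282099; 4600.0, 0.043937; 4400.0, 0.002995; 4200.0, 0.000089; 4000.0, 0.000001
##END=
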