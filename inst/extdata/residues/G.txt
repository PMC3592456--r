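# guanine: idealized synthetic planar template in the local base frame
# columns: atom <name> <element> <x> <y> <z> (Angstrom)
atom C5  C   -0.690    0.326    0.000
atom C6  C   -1.380   -0.869    0.000
atom N1  N   -0.690   -2.064    0.000
atom C2  C    0.690   -2.064    0.000
atom N3  N    1.380   -0.869    0.000
atom C4  C    0.690    0.326    0.000
atom N7  N   -1.116    1.639    0.000
atom C8  C    0.000    2.450    0.000
atom N9  N    1.116    1.639    0.000
atom O6  O   -2.620   -0.869    0.000
atom N2  N    1.360   -3.224    0.000
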