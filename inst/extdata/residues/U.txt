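# uracil: idealized synthetic planar template in the local base frame
# columns: atom <name> <element> <x> <y> <z> (Angstrom)
atom C4  C    0.000    2.450    0.000
atom C5  C   -1.195    1.760    0.000
atom C6  C   -1.195    0.380    0.000
atom N1  N   -0.000   -0.310    0.000
atom C2  C    1.195    0.380    0.000
atom N3  N    1.195    1.760    0.000
atom O2  O    2.269   -0.240    0.000
atom O4  O    0.000    3.690    0.000
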