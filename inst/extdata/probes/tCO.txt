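# tCO donor probe (tricyclic cytosine analogue): idealized synthetic planar template in the local base frame
# columns: atom <name> <element> <x> <y> <z> (Angstrom)
# dipole direction/center are documented idealized defaults, user-overridable
atom C4  C    0.000    2.450    0.000
atom C5  C   -1.195    1.760    0.000
atom C6  C   -1.195    0.380    0.000
atom N1  N   -0.000   -0.310    0.000
atom C2  C    1.195    0.380    0.000
atom N3  N    1.195    1.760    0.000
atom O2  O    2.269   -0.240    0.000
atom N4  N    0.000    3.790    0.000
atom O10 O   -2.350    1.450    0.000
atom C11 C   -3.550    0.750    0.000
code F
role donor
pairs_with G
dipole_center  -1.500  1.200  0.000
dipole_direction -0.866025 0.500000 0.000
bend_angle 8.2
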