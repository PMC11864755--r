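name	x	y	z
Fp1	-0.029339	0.090295	-0.003315
AF7	-0.055806	0.076810	-0.003315
AF3	-0.038593	0.082764	0.026186
F1	-0.027262	0.067475	0.061065
F3	-0.051776	0.063938	0.047500
F5	-0.069254	0.060202	0.024588
F7	-0.076810	0.055806	-0.003315
FT7	-0.090295	0.029339	-0.003315
FC5	-0.084349	0.032379	0.029357
FC3	-0.064256	0.034165	0.061065
FC1	-0.035597	0.035597	0.080565
C1	-0.037119	-0.000000	0.087448
C3	-0.068337	-0.000000	0.065993
C5	-0.088690	-0.000000	0.034045
T7	-0.094942	-0.000000	-0.003315
TP7	-0.090295	-0.029339	-0.003315
CP5	-0.084349	-0.032379	0.029357
CP3	-0.064256	-0.034165	0.061065
CP1	-0.035597	-0.035597	0.080565
P1	-0.027262	-0.067475	0.061065
P3	-0.051776	-0.063938	0.047500
P5	-0.069254	-0.060202	0.024588
P7	-0.076810	-0.055806	-0.003315
P9	-0.069656	-0.050608	-0.040149
PO7	-0.055806	-0.076810	-0.003315
PO3	-0.038593	-0.082764	0.026186
O1	-0.029339	-0.090295	-0.003315
Iz	0.000000	-0.086099	-0.040149
Oz	0.000000	-0.094942	-0.003315
POz	0.000000	-0.088690	0.034045
Pz	0.000000	-0.068337	0.065993
CPz	0.000000	-0.037119	0.087448
Fpz	0.000000	0.094942	-0.003315
Fp2	0.029339	0.090295	-0.003315
AF8	0.055806	0.076810	-0.003315
AF4	0.038593	0.082764	0.026186
AFz	0.000000	0.088690	0.034045
Fz	0.000000	0.068337	0.065993
F2	0.027262	0.067475	0.061065
F4	0.051776	0.063938	0.047500
F6	0.069254	0.060202	0.024588
F8	0.076810	0.055806	-0.003315
FT8	0.090295	0.029339	-0.003315
FC6	0.084349	0.032379	0.029357
FC4	0.064256	0.034165	0.061065
FC2	0.035597	0.035597	0.080565
FCz	0.000000	0.037119	0.087448
Cz	0.000000	0.000000	0.095000
C2	0.037119	0.000000	0.087448
C4	0.068337	0.000000	0.065993
C6	0.088690	0.000000	0.034045
T8	0.094942	0.000000	-0.003315
TP8	0.090295	-0.029339	-0.003315
CP6	0.084349	-0.032379	0.029357
CP4	0.064256	-0.034165	0.061065
CP2	0.035597	-0.035597	0.080565
P2	0.027262	-0.067475	0.061065
P4	0.051776	-0.063938	0.047500
P6	0.069254	-0.060202	0.024588
P8	0.076810	-0.055806	-0.003315
P10	0.069656	-0.050608	-0.040149
PO8	0.055806	-0.076810	-0.003315
PO4	0.038593	-0.082764	0.026186
O2	0.029339	-0.090295	-0.003315
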