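Activated B cell		IMM01_G01	IMM01_G02	IMM01_G03	IMM01_G04	IMM01_G05	IMM01_G06	IMM01_G07	IMM01_G08	IMM01_G09	IMM01_G10	IMM01_G11	IMM01_G12
Activated CD4 T cell		IMM02_G01	IMM02_G02	IMM02_G03	IMM02_G04	IMM02_G05	IMM02_G06	IMM02_G07	IMM02_G08	IMM02_G09	IMM02_G10	IMM02_G11	IMM02_G12
Activated CD8 T cell		IMM03_G01	IMM03_G02	IMM03_G03	IMM03_G04	IMM03_G05	IMM03_G06	IMM03_G07	IMM03_G08	IMM03_G09	IMM03_G10	IMM03_G11	IMM03_G12
Activated dendritic cell		IMM04_G01	IMM04_G02	IMM04_G03	IMM04_G04	IMM04_G05	IMM04_G06	IMM04_G07	IMM04_G08	IMM04_G09	IMM04_G10	IMM04_G11	IMM04_G12
CD56bright natural killer cell		IMM05_G01	IMM05_G02	IMM05_G03	IMM05_G04	IMM05_G05	IMM05_G06	IMM05_G07	IMM05_G08	IMM05_G09	IMM05_G10	IMM05_G11	IMM05_G12
CD56dim natural killer cell		IMM06_G01	IMM06_G02	IMM06_G03	IMM06_G04	IMM06_G05	IMM06_G06	IMM06_G07	IMM06_G08	IMM06_G09	IMM06_G10	IMM06_G11	IMM06_G12
Central memory CD4 T cell		IMM07_G01	IMM07_G02	IMM07_G03	IMM07_G04	IMM07_G05	IMM07_G06	IMM07_G07	IMM07_G08	IMM07_G09	IMM07_G10	IMM07_G11	IMM07_G12
Central memory CD8 T cell		IMM08_G01	IMM08_G02	IMM08_G03	IMM08_G04	IMM08_G05	IMM08_G06	IMM08_G07	IMM08_G08	IMM08_G09	IMM08_G10	IMM08_G11	IMM08_G12
Effector memory CD4 T cell		IMM09_G01	IMM09_G02	IMM09_G03	IMM09_G04	IMM09_G05	IMM09_G06	IMM09_G07	IMM09_G08	IMM09_G09	IMM09_G10	IMM09_G11	IMM09_G12
Effector memory CD8 T cell		IMM10_G01	IMM10_G02	IMM10_G03	IMM10_G04	IMM10_G05	IMM10_G06	IMM10_G07	IMM10_G08	IMM10_G09	IMM10_G10	IMM10_G11	IMM10_G12
Eosinophil		IMM11_G01	IMM11_G02	IMM11_G03	IMM11_G04	IMM11_G05	IMM11_G06	IMM11_G07	IMM11_G08	IMM11_G09	IMM11_G10	IMM11_G11	IMM11_G12
Gamma delta T cell		IMM12_G01	IMM12_G02	IMM12_G03	IMM12_G04	IMM12_G05	IMM12_G06	IMM12_G07	IMM12_G08	IMM12_G09	IMM12_G10	IMM12_G11	IMM12_G12
Immature B cell		IMM13_G01	IMM13_G02	IMM13_G03	IMM13_G04	IMM13_G05	IMM13_G06	IMM13_G07	IMM13_G08	IMM13_G09	IMM13_G10	IMM13_G11	IMM13_G12
Immature dendritic cell		IMM14_G01	IMM14_G02	IMM14_G03	IMM14_G04	IMM14_G05	IMM14_G06	IMM14_G07	IMM14_G08	IMM14_G09	IMM14_G10	IMM14_G11	IMM14_G12
Macrophage		IMM15_G01	IMM15_G02	IMM15_G03	IMM15_G04	IMM15_G05	IMM15_G06	IMM15_G07	IMM15_G08	IMM15_G09	IMM15_G10	IMM15_G11	IMM15_G12
Mast cell		IMM16_G01	IMM16_G02	IMM16_G03	IMM16_G04	IMM16_G05	IMM16_G06	IMM16_G07	IMM16_G08	IMM16_G09	IMM16_G10	IMM16_G11	IMM16_G12
MDSC		IMM17_G01	IMM17_G02	IMM17_G03	IMM17_G04	IMM17_G05	IMM17_G06	IMM17_G07	IMM17_G08	IMM17_G09	IMM17_G10	IMM17_G11	IMM17_G12
Memory B cell		IMM18_G01	IMM18_G02	IMM18_G03	IMM18_G04	IMM18_G05	IMM18_G06	IMM18_G07	IMM18_G08	IMM18_G09	IMM18_G10	IMM18_G11	IMM18_G12
Monocyte		IMM19_G01	IMM19_G02	IMM19_G03	IMM19_G04	IMM19_G05	IMM19_G06	IMM19_G07	IMM19_G08	IMM19_G09	IMM19_G10	IMM19_G11	IMM19_G12
Natural killer cell		IMM20_G01	IMM20_G02	IMM20_G03	IMM20_G04	IMM20_G05	IMM20_G06	IMM20_G07	IMM20_G08	IMM20_G09	IMM20_G10	IMM20_G11	IMM20_G12
Natural killer T cell		IMM21_G01	IMM21_G02	IMM21_G03	IMM21_G04	IMM21_G05	IMM21_G06	IMM21_G07	IMM21_G08	IMM21_G09	IMM21_G10	IMM21_G11	IMM21_G12
Neutrophil		IMM22_G01	IMM22_G02	IMM22_G03	IMM22_G04	IMM22_G05	IMM22_G06	IMM22_G07	IMM22_G08	IMM22_G09	IMM22_G10	IMM22_G11	IMM22_G12
Plasmacytoid dendritic cell		IMM23_G01	IMM23_G02	IMM23_G03	IMM23_G04	IMM23_G05	IMM23_G06	IMM23_G07	IMM23_G08	IMM23_G09	IMM23_G10	IMM23_G11	IMM23_G12
Regulatory T cell		IMM24_G01	IMM24_G02	IMM24_G03	IMM24_G04	IMM24_G05	IMM24_G06	IMM24_G07	IMM24_G08	IMM24_G09	IMM24_G10	IMM24_G11	IMM24_G12
T follicular helper cell		IMM25_G01	IMM25_G02	IMM25_G03	IMM25_G04	IMM25_G05	IMM25_G06	IMM25_G07	IMM25_G08	IMM25_G09	IMM25_G10	IMM25_G11	IMM25_G12
Type 1 T helper cell		IMM26_G01	IMM26_G02	IMM26_G03	IMM26_G04	IMM26_G05	IMM26_G06	IMM26_G07	IMM26_G08	IMM26_G09	IMM26_G10	IMM26_G11	IMM26_G12
Type 17 T helper cell		IMM27_G01	IMM27_G02	IMM27_G03	IMM27_G04	IMM27_G05	IMM27_G06	IMM27_G07	IMM27_G08	IMM27_G09	IMM27_G10	IMM27_G11	IMM27_G12
Type 2 T helper cell		IMM28_G01	IMM28_G02	IMM28_G03	IMM28_G04	IMM28_G05	IMM28_G06	IMM28_G07	IMM28_G08	IMM28_G09	IMM28_G10	IMM28_G11	IMM28_G12
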