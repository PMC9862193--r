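{
  "role": "estimated",
  "description": "Kinetic constants for the yeast glycolysis/trehalose-cycle feast-famine model",
  "values": {
    "HXT.Vmax": 1.7,
    "HXT.Km": 0.9,
    "HXT.Ki": 0.02,
    "HXT.Keq": 1,
    "HXT.GLCec_min": 0.5,
    "HXT.sensing": 1,
    "HXK.Vmax": 15.75,
    "HXK.Km_GLC": 0.11,
    "HXK.Km_ATP": 0.15,
    "HXK.Km_G6P": 30,
    "HXK.Km_ADP": 1,
    "HXK.Ki_T6P": 0.0183,
    "HXK.Keq": 2000,
    "PGI.Vmax": 7.72756280487805,
    "PGI.Km_G6P": 8,
    "PGI.Km_F6P": 2.4,
    "PGI.Keq": 0.29,
    "PFK.Vmax": 6.35743066792442,
    "PFK.Km_F6P": 2,
    "PFK.Km_ATP": 0.3,
    "PFK.L0": 6,
    "PFK.Ki_ATP": 1,
    "PFK.Ka_AMP": 1,
    "PFK.Ka_FBP": 0.05,
    "PFK.n": 4,
    "FBA.Vmax": 11.0210098684211,
    "FBA.Km_FBP": 1.5,
    "FBA.Km_DHAP": 3,
    "FBA.Km_GAP": 0.3,
    "FBA.Keq": 0.069,
    "TPI.Vmax": 14.1487178571429,
    "TPI.Km_DHAP": 3,
    "TPI.Km_GAP": 1.4,
    "TPI.Keq": 0.1,
    "GAPDH.Vmax": 10.6085426086957,
    "GAPDH.Km_GAP": 0.25,
    "GAPDH.Km_NAD": 0.3,
    "GAPDH.Km_BPG": 0.15,
    "GAPDH.Km_NADH": 0.3,
    "GAPDH.Km_PI": 5,
    "GAPDH.Keq": 0.3,
    "PGK.Vmax": 16.4675986885246,
    "PGK.Km_BPG": 0.15,
    "PGK.Km_ADP": 0.5,
    "PGK.Km_P3G": 5,
    "PGK.Km_ATP": 1,
    "PGK.Keq": 3200,
    "GPM.Vmax": 16.5326823529412,
    "GPM.Km_P3G": 9,
    "GPM.Km_P2G": 1.2,
    "GPM.Keq": 0.19,
    "ENO.Vmax": 38.1188769230769,
    "ENO.Km_P2G": 1.2,
    "ENO.Km_PEP": 7,
    "ENO.Keq": 6.7,
    "PYK.Vmax": 7.30278733598692,
    "PYK.K05": 2,
    "PYK.n": 3,
    "PYK.Km_ADP": 0.53,
    "PYK.Ka_FBP": 0.5,
    "PDC.Vmax": 0.1218,
    "PDC.K05": 1.2,
    "PDC.n": 2,
    "ADH.Vmax": 0.135,
    "ADH.Km_ACE": 2.4,
    "ADH.Km_NADH": 0.3,
    "G3PDH.Vmax": 0.792,
    "G3PDH.Km_DHAP": 3,
    "G3PDH.Km_NADH": 0.3,
    "GPP.Vmax": 0.264,
    "GPP.Km_G3P": 1.5,
    "GLYC_EX.k": 0.00253968253968254,
    "PGM1.Vmax": 0.212008259259259,
    "PGM1.Km_G6P": 8,
    "PGM1.Km_G1P": 1.2,
    "PGM1.Keq": 0.17,
    "UGP.Vmax": 1.25018678707224,
    "UGP.Km_G1P": 1.2,
    "UGP.Km_ATP": 0.5,
    "UGP.Kia_G1P": 1.2,
    "UGP.Km_UDPG": 3,
    "UGP.Km_ADP": 3,
    "UGP.Keq": 50,
    "TPS1.Vmax": 0.122369642857143,
    "TPS1.Km_G6P": 2,
    "TPS1.Km_UDPG": 0.9,
    "TPS2.Vmax": 3.709825,
    "TPS2.Km_T6P": 3,
    "NTH1.Vmax": 0.0651,
    "NTH1.Km_TRE": 0.13,
    "AGT1.Vmax": 0.0063242350409836,
    "AGT1.Km_cyt": 1.5,
    "AGT1.Km_ec": 10,
    "AGT1.Keq": 1,
    "AGT1.Ki_T6P": 1,
    "VACT.Vmax": 4.21604999999998,
    "VACT.Km_cyt": 1.5,
    "VACT.Km_vac": 30,
    "VACT.Keq": 30,
    "ATH1.Vmax": 0.00480649315068493,
    "ATH1.Km_TRE": 1.2,
    "ATH1.Ki_T6P": 1,
    "GLY_SYNTH.Ksat_UDPG": 0.1,
    "GLY_SYNTH.Ki_GLY": 60,
    "GLY_SYNTH.h": 10,
    "GLY_DEG.Ksat_GLY": 5,
    "ATPase.k": 1.43365,
    "ATPase.Km": 2.5,
    "ATPase.n": 6,
    "ADK.k": 10,
    "ADK.Keq": 1,
    "MITO_NADH.Vmax": 5.62815,
    "MITO_NADH.Km_NADH": 1.2,
    "MITO_NADH.Km_ADP": 0.5,
    "PIBUF.k": 0.05,
    "PIBUF.Pi_ref": 27.593,
    "sink_G6P.Vmax": 0.33,
    "sink_G6P.Km": 8,
    "sink_P3G.Vmax": 0.385,
    "sink_P3G.Km": 9,
    "sink_PYR.Vmax": 7.7,
    "sink_PYR.Km": 12,
    "sink_PYR.f": 0.5,
    "sink_ACE.Vmax": 0.614900000000001,
    "sink_ACE.Km": 3
  },
  "units": {
    "HXT.Vmax": "mM/s",
    "HXT.Km": "mM",
    "HXT.Ki": "mM",
    "HXT.Keq": "1",
    "HXT.GLCec_min": "mM",
    "HXT.sensing": "1",
    "HXK.Vmax": "mM/s",
    "HXK.Km_GLC": "mM",
    "HXK.Km_ATP": "mM",
    "HXK.Km_G6P": "mM",
    "HXK.Km_ADP": "mM",
    "HXK.Ki_T6P": "mM",
    "HXK.Keq": "1",
    "PGI.Vmax": "mM/s",
    "PGI.Km_G6P": "mM",
    "PGI.Km_F6P": "mM",
    "PGI.Keq": "1",
    "PFK.Vmax": "mM/s",
    "PFK.Km_F6P": "mM",
    "PFK.Km_ATP": "mM",
    "PFK.L0": "1",
    "PFK.Ki_ATP": "mM",
    "PFK.Ka_AMP": "mM",
    "PFK.Ka_FBP": "mM",
    "PFK.n": "1",
    "FBA.Vmax": "mM/s",
    "FBA.Km_FBP": "mM",
    "FBA.Km_DHAP": "mM",
    "FBA.Km_GAP": "mM",
    "FBA.Keq": "1",
    "TPI.Vmax": "mM/s",
    "TPI.Km_DHAP": "mM",
    "TPI.Km_GAP": "mM",
    "TPI.Keq": "1",
    "GAPDH.Vmax": "mM/s",
    "GAPDH.Km_GAP": "mM",
    "GAPDH.Km_NAD": "mM",
    "GAPDH.Km_BPG": "mM",
    "GAPDH.Km_NADH": "mM",
    "GAPDH.Km_PI": "mM",
    "GAPDH.Keq": "1",
    "PGK.Vmax": "mM/s",
    "PGK.Km_BPG": "mM",
    "PGK.Km_ADP": "mM",
    "PGK.Km_P3G": "mM",
    "PGK.Km_ATP": "mM",
    "PGK.Keq": "1",
    "GPM.Vmax": "mM/s",
    "GPM.Km_P3G": "mM",
    "GPM.Km_P2G": "mM",
    "GPM.Keq": "1",
    "ENO.Vmax": "mM/s",
    "ENO.Km_P2G": "mM",
    "ENO.Km_PEP": "mM",
    "ENO.Keq": "1",
    "PYK.Vmax": "mM/s",
    "PYK.K05": "mM",
    "PYK.n": "1",
    "PYK.Km_ADP": "mM",
    "PYK.Ka_FBP": "mM",
    "PDC.Vmax": "mM/s",
    "PDC.K05": "mM",
    "PDC.n": "1",
    "ADH.Vmax": "mM/s",
    "ADH.Km_ACE": "mM",
    "ADH.Km_NADH": "mM",
    "G3PDH.Vmax": "mM/s",
    "G3PDH.Km_DHAP": "mM",
    "G3PDH.Km_NADH": "mM",
    "GPP.Vmax": "mM/s",
    "GPP.Km_G3P": "mM",
    "GLYC_EX.k": "1/s",
    "PGM1.Vmax": "mM/s",
    "PGM1.Km_G6P": "mM",
    "PGM1.Km_G1P": "mM",
    "PGM1.Keq": "1",
    "UGP.Vmax": "mM/s",
    "UGP.Km_G1P": "mM",
    "UGP.Km_ATP": "mM",
    "UGP.Kia_G1P": "mM",
    "UGP.Km_UDPG": "mM",
    "UGP.Km_ADP": "mM",
    "UGP.Keq": "1",
    "TPS1.Vmax": "mM/s",
    "TPS1.Km_G6P": "mM",
    "TPS1.Km_UDPG": "mM",
    "TPS2.Vmax": "mM/s",
    "TPS2.Km_T6P": "mM",
    "NTH1.Vmax": "mM/s",
    "NTH1.Km_TRE": "mM",
    "AGT1.Vmax": "mM/s",
    "AGT1.Km_cyt": "mM",
    "AGT1.Km_ec": "mM",
    "AGT1.Keq": "1",
    "AGT1.Ki_T6P": "mM",
    "VACT.Vmax": "mM/s",
    "VACT.Km_cyt": "mM",
    "VACT.Km_vac": "mM",
    "VACT.Keq": "1",
    "ATH1.Vmax": "mM/s",
    "ATH1.Km_TRE": "mM",
    "ATH1.Ki_T6P": "mM",
    "GLY_SYNTH.Ksat_UDPG": "mM",
    "GLY_SYNTH.Ki_GLY": "mM",
    "GLY_SYNTH.h": "1",
    "GLY_DEG.Ksat_GLY": "mM",
    "ATPase.k": "mM/s",
    "ATPase.Km": "mM",
    "ATPase.n": "1",
    "ADK.k": "1/(mM.s)",
    "ADK.Keq": "1",
    "MITO_NADH.Vmax": "mM/s",
    "MITO_NADH.Km_NADH": "mM",
    "MITO_NADH.Km_ADP": "mM",
    "PIBUF.k": "1/s",
    "PIBUF.Pi_ref": "mM",
    "sink_G6P.Vmax": "mM/s",
    "sink_G6P.Km": "mM",
    "sink_P3G.Vmax": "mM/s",
    "sink_P3G.Km": "mM",
    "sink_PYR.Vmax": "mM/s",
    "sink_PYR.Km": "mM",
    "sink_PYR.f": "1",
    "sink_ACE.Vmax": "mM/s",
    "sink_ACE.Km": "mM"
  }
}
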