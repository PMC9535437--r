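{
  "heart_rate_bpm": 69,
  "dt_s": 0.001,
  "compartments": [
    {
      "name": "PV",
      "elastance_mmHg_L": 60,
      "unstressed_volume_L": 0.3,
      "volume_L": 0.424284930907107
    },
    {
      "name": "LA",
      "elastance_profile": {
        "ees_mmHg_L": 280,
        "ed_mmHg_L": 70,
        "alpha1_frac": 0.1,
        "n1": 1.9,
        "alpha2_frac": 0.17,
        "n2": 13,
        "shift_frac": 0.85
      },
      "unstressed_volume_L": 0.0154,
      "volume_L": 0.0418213164906173
    },
    {
      "name": "LV",
      "elastance_profile": {
        "ees_mmHg_L": 2800,
        "ed_mmHg_L": 50,
        "alpha1_frac": 0.303,
        "n1": 1.32,
        "alpha2_frac": 0.508,
        "n2": 21.9,
        "shift_frac": 0
      },
      "unstressed_volume_L": 0.0198,
      "volume_L": 0.137607623862448
    },
    {
      "name": "AA",
      "elastance_mmHg_L": 3000,
      "unstressed_volume_L": 0.06,
      "volume_L": 0.0817288869338821
    },
    {
      "name": "AD",
      "elastance_mmHg_L": 1500,
      "unstressed_volume_L": 0.15,
      "volume_L": 0.193588026781523
    },
    {
      "name": "UB",
      "elastance_mmHg_L": 250,
      "unstressed_volume_L": 0.5,
      "volume_L": 0.659155586928493
    },
    {
      "name": "LB",
      "elastance_mmHg_L": 250,
      "unstressed_volume_L": 0.6,
      "volume_L": 0.760446919598474
    },
    {
      "name": "AR",
      "elastance_mmHg_L": 1383.99738485071,
      "unstressed_volume_L": 0.00257694555290309,
      "volume_L": 0.0525280720236872
    },
    {
      "name": "GL",
      "elastance_mmHg_L": 1000,
      "unstressed_volume_L": 0.0156,
      "volume_L": 0.0706809722776829
    },
    {
      "name": "TU",
      "elastance_mmHg_L": 1500,
      "unstressed_volume_L": 0.0195,
      "volume_L": 0.0302576843971322
    },
    {
      "name": "VR",
      "elastance_mmHg_L": 300,
      "unstressed_volume_L": 0.052,
      "volume_L": 0.08318523507893
    },
    {
      "name": "UA",
      "elastance_mmHg_L": 2000,
      "unstressed_volume_L": 0.0105,
      "volume_L": 0.0484685715014394
    },
    {
      "name": "SA",
      "elastance_mmHg_L": 1500,
      "unstressed_volume_L": 0.0105,
      "volume_L": 0.0366569211533662
    },
    {
      "name": "PL",
      "elastance_mmHg_L": 500,
      "unstressed_volume_L": 0.03,
      "volume_L": 0.0714075258058802
    },
    {
      "name": "UV",
      "elastance_mmHg_L": 300,
      "unstressed_volume_L": 0.03,
      "volume_L": 0.0575284007243732
    },
    {
      "name": "VC",
      "elastance_mmHg_L": 60,
      "unstressed_volume_L": 1.2,
      "volume_L": 1.30185022103872
    },
    {
      "name": "RA",
      "elastance_profile": {
        "ees_mmHg_L": 250,
        "ed_mmHg_L": 60,
        "alpha1_frac": 0.1,
        "n1": 1.9,
        "alpha2_frac": 0.17,
        "n2": 13,
        "shift_frac": 0.85
      },
      "unstressed_volume_L": 0.0154,
      "volume_L": 0.0366265567793704
    },
    {
      "name": "RV",
      "elastance_profile": {
        "ees_mmHg_L": 700,
        "ed_mmHg_L": 30,
        "alpha1_frac": 0.303,
        "n1": 1.32,
        "alpha2_frac": 0.508,
        "n2": 21.9,
        "shift_frac": 0
      },
      "unstressed_volume_L": 0.0242,
      "volume_L": 0.133879429792553
    },
    {
      "name": "PA",
      "elastance_mmHg_L": 900,
      "unstressed_volume_L": 0.05,
      "volume_L": 0.0580189963784398
    }
  ],
  "connectors": [
    {
      "name": "PV_LA",
      "source": "PV",
      "target": "LA",
      "resistance_mmHg_s_L": 15,
      "valve": false
    },
    {
      "name": "LA_LV",
      "source": "LA",
      "target": "LV",
      "resistance_mmHg_s_L": 12,
      "valve": true
    },
    {
      "name": "LV_AA",
      "source": "LV",
      "target": "AA",
      "resistance_mmHg_s_L": 35,
      "valve": true
    },
    {
      "name": "AA_AD",
      "source": "AA",
      "target": "AD",
      "resistance_mmHg_s_L": 15,
      "valve": false
    },
    {
      "name": "AA_UB",
      "source": "AA",
      "target": "UB",
      "resistance_mmHg_s_L": 1080.76977000295,
      "valve": false
    },
    {
      "name": "UB_VC",
      "source": "UB",
      "target": "VC",
      "resistance_mmHg_s_L": 888.67604068465,
      "valve": false
    },
    {
      "name": "AD_LB",
      "source": "AD",
      "target": "LB",
      "resistance_mmHg_s_L": 1043.90329669944,
      "valve": false
    },
    {
      "name": "LB_VC",
      "source": "LB",
      "target": "VC",
      "resistance_mmHg_s_L": 888.67604068465,
      "valve": false
    },
    {
      "name": "AD_AR",
      "source": "AD",
      "target": "AR",
      "resistance_mmHg_s_L": 262.898101287729,
      "valve": false
    },
    {
      "name": "AR_GL",
      "source": "AR",
      "target": "GL",
      "resistance_mmHg_s_L": 1343.70140658172,
      "valve": false
    },
    {
      "name": "GL_VR",
      "source": "GL",
      "target": "VR",
      "resistance_mmHg_s_L": 3226.83076913901,
      "valve": false
    },
    {
      "name": "GL_TU",
      "source": "GL",
      "target": "TU",
      "resistance_mmHg_s_L": 15683.3322868202,
      "valve": false
    },
    {
      "name": "TU_VR",
      "source": "TU",
      "target": "VR",
      "resistance_mmHg_s_L": 2744.85091677817,
      "valve": false
    },
    {
      "name": "VR_VC",
      "source": "VR",
      "target": "VC",
      "resistance_mmHg_s_L": 245.37156120188,
      "valve": false
    },
    {
      "name": "AD_UA",
      "source": "AD",
      "target": "UA",
      "resistance_mmHg_s_L": 5500,
      "valve": false
    },
    {
      "name": "UA_SA",
      "source": "UA",
      "target": "SA",
      "resistance_mmHg_s_L": 38000,
      "valve": false
    },
    {
      "name": "SA_PL",
      "source": "SA",
      "target": "PL",
      "resistance_mmHg_s_L": 19000,
      "valve": false
    },
    {
      "name": "PL_UV",
      "source": "PL",
      "target": "UV",
      "resistance_mmHg_s_L": 13000,
      "valve": false
    },
    {
      "name": "UV_VC",
      "source": "UV",
      "target": "VC",
      "resistance_mmHg_s_L": 3200,
      "valve": false
    },
    {
      "name": "VC_RA",
      "source": "VC",
      "target": "RA",
      "resistance_mmHg_s_L": 10,
      "valve": false
    },
    {
      "name": "RA_RV",
      "source": "RA",
      "target": "RV",
      "resistance_mmHg_s_L": 12,
      "valve": true
    },
    {
      "name": "RV_PA",
      "source": "RV",
      "target": "PA",
      "resistance_mmHg_s_L": 35,
      "valve": true
    },
    {
      "name": "PA_PV",
      "source": "PA",
      "target": "PV",
      "resistance_mmHg_s_L": 55,
      "valve": false
    }
  ],
  "autoregulation": {
    "mode": "none",
    "mr": {
      "p0": 80,
      "p1": 180,
      "q0": 0.018,
      "k": 0.5,
      "delta1": 0.3,
      "delta2": 1.2,
      "tau1": 4,
      "tau2": 5.3,
      "gain": 1,
      "r_base": 1343.70140658172,
      "floor_frac": 0.05,
      "tau_convention": "physiological"
    },
    "tgf": {
      "op_gfr": 149,
      "th_gfr": 144,
      "sa_gfr": 333,
      "delta3": 18,
      "tau3": 15,
      "tau4": 33,
      "gain": 49.4415848459849,
      "gain_units": "(mmHg*s/L)/(ml/min)",
      "sensing": "instantaneous"
    }
  },
  "calibration": {
    "targets": {
      "co_l_min": 5.8,
      "map_mmHg": 82.7,
      "rbf_l_min": 1,
      "gfr_l_min": 0.149,
      "co_range_l_min": [
        5.7,
        6
      ]
    },
    "achieved": {
      "p_vc": 5.2182430609654
    },
    "calibrated": true
  },
  "gestation": {
    "applied": true,
    "multipliers": {
      "heart": 1.1,
      "renal": 1.3,
      "uterine": 1.5,
      "plasma_stressed": 1.12
    }
  }
}
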