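{
  "comment": "Polymer and solute properties (molecular weight, hydrodynamic radius, literature coil overlap concentration). rg_nm is null where no gyration radius is tabulated.",
  "polymers": [
    {"name": "dextran500", "mw_kda": 500, "rh_nm": 15.9, "rg_nm": null, "cstar_percent": 2.5},
    {"name": "dextran70",  "mw_kda": 70,  "rh_nm": 5.8,  "rg_nm": null, "cstar_percent": 6.9},
    {"name": "ficoll400",  "mw_kda": 400, "rh_nm": 8.0,  "rg_nm": null, "cstar_percent": 9.1}
  ],
  "solutes": [
    {"name": "rnase", "mw_kda": 13.7, "rh_nm": 1.8}
  ]
}
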