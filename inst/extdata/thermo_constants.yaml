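# Standard-state thermodynamic properties of aqueous species at 25 C, 1 bar.
# gibbs_kj / enthalpy_kj are apparent standard molal Gibbs energy and enthalpy
# of formation from the elements, in kJ/mol. Temperature extrapolation inside
# the package is van't Hoff from these 25 C anchors (valid for the 0-50 C
# range of dilute near-surface fluids).
gas_constant: 8.314         # J/(mol K), universal gas constant
reference_temperature_c: 25.0
davies_a:
  # Debye-Hueckel limiting-law A parameter (log10 basis) at 1 bar /
  # liquid-vapor saturation, interpolated linearly in temperature.
  temperature_c: [0.0, 25.0, 50.0, 75.0, 100.0]
  value: [0.4918, 0.5092, 0.5336, 0.5639, 0.5998]
  source: "Helgeson, Kirkham & Flowers (1981), Am. J. Sci. 281"
species:
  "H2O":
    charge: 0
    gibbs_kj: -237.18
    enthalpy_kj: -285.83
    source: "CODATA key values (Cox et al. 1989); liquid water"
  "H+":
    charge: 1
    gibbs_kj: 0.0
    enthalpy_kj: 0.0
    source: "convention (hydrogen-ion reference)"
  "OH-":
    charge: -1
    gibbs_kj: -157.30
    enthalpy_kj: -230.02
    source: "Shock & Helgeson (1988), GCA 52"
  "H2":
    charge: 0
    gibbs_kj: 17.72
    enthalpy_kj: -4.04
    source: "Shock et al. (1989), GCA 53; H2(aq)"
  "CH4":
    charge: 0
    gibbs_kj: -34.45
    enthalpy_kj: -87.91
    source: "Shock & Helgeson (1990), GCA 54; CH4(aq)"
  "CO2":
    charge: 0
    gibbs_kj: -385.97
    enthalpy_kj: -413.84
    source: "Shock & Helgeson (1988), GCA 52; CO2(aq)"
  "HCO3-":
    charge: -1
    gibbs_kj: -586.94
    enthalpy_kj: -689.93
    source: "Shock & Helgeson (1988), GCA 52"
  "CO3-2":
    charge: -2
    gibbs_kj: -527.98
    enthalpy_kj: -675.23
    source: "Shock & Helgeson (1988), GCA 52"
  "HCOOH":
    charge: 0
    gibbs_kj: -372.30
    enthalpy_kj: -425.43
    source: "Shock (1995), Am. J. Sci. 295; formic acid(aq)"
  "HCOO-":
    charge: -1
    gibbs_kj: -350.88
    enthalpy_kj: -425.55
    source: "Shock (1995), Am. J. Sci. 295; formate anion"
  "CH3COOH":
    charge: 0
    gibbs_kj: -396.48
    enthalpy_kj: -485.76
    source: "Shock (1995), Am. J. Sci. 295; acetic acid(aq)"
  "CH3COO-":
    charge: -1
    gibbs_kj: -369.32
    enthalpy_kj: -486.01
    source: "Shock (1995), Am. J. Sci. 295; acetate anion"
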