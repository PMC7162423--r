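{
  "isotope": "Pb-212",
  "provenance": "Mean emission energies and branch fractions assembled from NNDC NuDat / ICRP Publication 107 decay data for the Pb-212 -> Bi-212 -> {Po-212, Tl-208} -> Pb-208 chain; beta energies are spectrum means, gamma entries are summed mean photon energy per decay of the step.",
  "half_life_h": 10.64,
  "steps": [
    {
      "name": "Pb-212 beta",
      "occupancy": 1.0,
      "branches": {
        "fraction": [1.0],
        "energy_mev": [0.102],
        "class": ["beta"]
      }
    },
    {
      "name": "Pb-212 gamma",
      "occupancy": 1.0,
      "branches": {
        "fraction": [1.0],
        "energy_mev": [0.115],
        "class": ["gamma"]
      }
    },
    {
      "name": "Bi-212",
      "occupancy": 1.0,
      "branches": {
        "fraction": [0.3594, 0.6406],
        "energy_mev": [6.062, 0.492],
        "class": ["alpha", "beta"]
      }
    },
    {
      "name": "Bi-212 gamma",
      "occupancy": 1.0,
      "branches": {
        "fraction": [1.0],
        "energy_mev": [0.104],
        "class": ["gamma"]
      }
    },
    {
      "name": "Po-212 alpha",
      "occupancy": 0.6406,
      "branches": {
        "fraction": [1.0],
        "energy_mev": [8.785],
        "class": ["alpha"]
      }
    },
    {
      "name": "Tl-208 beta",
      "occupancy": 0.3594,
      "branches": {
        "fraction": [1.0],
        "energy_mev": [0.560],
        "class": ["beta"]
      }
    },
    {
      "name": "Tl-208 gamma",
      "occupancy": 0.3594,
      "branches": {
        "fraction": [1.0],
        "energy_mev": [3.375],
        "class": ["gamma"]
      }
    }
  ]
}
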