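{
  "type": "scenario",
  "name": "ergaster",
  "units": {
    "mass": "kg",
    "energy": "MJ",
    "time": "yr",
    "skill": "TB"
  },
  "parameters": {
    "Bb": 313,
    "Br": 2697,
    "Bs": 30,
    "Bk": 50,
    "Ek": 250,
    "Eb": 300,
    "Er": 50,
    "Es": 25,
    "sk": 0.5,
    "kleiberCoef": 125,
    "kleiberExp": 0.75,
    "alpha": 1.15,
    "gamma": 0.6,
    "nu": 1.5,
    "compBase": 1.2,
    "competenceForm": "power",
    "cooperationForm": "additive",
    "challengeMix": [0.55, 0.35, 0, 0.1],
    "p": 0.9985,
    "newborn": [0.15, 0.001, 1.35]
  },
  "grid": {
    "binWidth": 0.1,
    "maxAge": 47
  }
}
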