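{
  "modules": {},
  "signals": {
    "OUT": 4
  },
  "transistors": [
    {
      "c1": 4,
      "c2": 5,
      "gate": 2,
      "id": 0,
      "x": 0,
      "y": 0
    },
    {
      "c1": 5,
      "c2": 1,
      "gate": 3,
      "id": 1,
      "x": 4,
      "y": 0
    }
  ],
  "wires": [
    {
      "id": 0,
      "name": "vcc",
      "pullup": false,
      "role": "power"
    },
    {
      "id": 1,
      "name": "vss",
      "pullup": false,
      "role": "ground"
    },
    {
      "id": 2,
      "name": "a",
      "pullup": false,
      "role": "input"
    },
    {
      "id": 3,
      "name": "b",
      "pullup": false,
      "role": "input"
    },
    {
      "id": 4,
      "name": "out",
      "pullup": true,
      "role": "output"
    },
    {
      "id": 5,
      "name": "out.m5",
      "pullup": false,
      "role": "plain"
    }
  ]
}
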