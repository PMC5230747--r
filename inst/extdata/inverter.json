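{
  "modules": {},
  "signals": {},
  "transistors": [
    {
      "c1": 3,
      "c2": 1,
      "gate": 2,
      "id": 0,
      "x": 0,
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
      "name": "in",
      "pullup": false,
      "role": "input"
    },
    {
      "id": 3,
      "name": "out",
      "pullup": true,
      "role": "output"
    }
  ]
}
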