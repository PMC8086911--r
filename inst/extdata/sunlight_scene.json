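{
  "profile": [
    {
      "elevation": -90,
      "red": 16.75,
      "green": 16.65,
      "blue": 16.5
    },
    {
      "elevation": -15,
      "red": 16.95,
      "green": 16.85,
      "blue": 16.75
    },
    {
      "elevation": 0,
      "red": 16.5,
      "green": 16.5,
      "blue": 16.5
    },
    {
      "elevation": 15,
      "red": 17.1,
      "green": 17.25,
      "blue": 17.4
    },
    {
      "elevation": 90,
      "red": 17.35,
      "green": 17.6,
      "blue": 17.8
    }
  ],
  "sigma": 0.3,
  "sources": [],
  "name": "sunlight",
  "seed": 100
}
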