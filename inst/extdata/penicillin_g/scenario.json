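{
  "format_version": "1.0",
  "name": "penicillin G 250 mg/g oral powder",
  "ai_content": 250,
  "route": "oral, drinking water",
  "regimens": [
    {
      "species": "piglet",
      "dose": 25,
      "duration": 4
    },
    {
      "species": "chicken",
      "dose": 10,
      "duration": 4
    },
    {
      "species": "turkey",
      "dose": 10,
      "duration": 4
    }
  ],
  "sediment_override": 1721
}
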