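{
  "fps": 30,
  "movies": [
    {
      "name": "Floating Bubbles",
      "type": "nonsocial",
      "duration_s": 35,
      "social_side": "none"
    },
    {
      "name": "Dog in Grass",
      "type": "nonsocial",
      "duration_s": 16,
      "social_side": "none"
    },
    {
      "name": "Dog in Grass RRL",
      "type": "nonsocial",
      "duration_s": 40,
      "social_side": "none"
    },
    {
      "name": "Spinning Top",
      "type": "mixed",
      "duration_s": 53,
      "social_side": "right"
    },
    {
      "name": "Mechanical Puppy",
      "type": "nonsocial",
      "duration_s": 25,
      "social_side": "none"
    },
    {
      "name": "Blowing Bubbles",
      "type": "mixed",
      "duration_s": 64,
      "social_side": "left"
    },
    {
      "name": "Rhymes",
      "type": "social",
      "duration_s": 30,
      "social_side": "none"
    },
    {
      "name": "Toys",
      "type": "nonsocial",
      "duration_s": 19,
      "social_side": "none"
    },
    {
      "name": "Make Me Laugh",
      "type": "social",
      "duration_s": 56,
      "social_side": "none"
    },
    {
      "name": "Playing with Blocks",
      "type": "social",
      "duration_s": 71,
      "social_side": "none"
    },
    {
      "name": "Fun at the Park",
      "type": "social",
      "duration_s": 51,
      "social_side": "none"
    }
  ]
}
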