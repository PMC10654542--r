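[
  {
    "hypothesis": "H1",
    "response": "interrupted_escape",
    "family": "binomial",
    "filter_a": "behavior == 'divert'",
    "filter_b": "behavior == 'attack'",
    "description": "more interrupted escapes when the threat diverts"
  },
  {
    "hypothesis": "H2",
    "response": "escape_initiation_time",
    "family": "gaussian",
    "filter_a": "behavior == 'attack' & tti == 'short'",
    "filter_b": "behavior == 'attack' & tti == 'long'",
    "description": "earlier initiation under short time-to-impact when attacked"
  },
  {
    "hypothesis": "H3",
    "response": "initiated_escape",
    "family": "binomial",
    "filter_a": "behavior == 'divert' & tti == 'short'",
    "filter_b": "behavior == 'divert' & tti == 'long'",
    "description": "more initiations under short time-to-impact when threat diverts"
  },
  {
    "hypothesis": "H4",
    "response": "escaped_to_shelter",
    "family": "binomial",
    "filter_a": "behavior == 'attack' & tti == 'short' & threat %in% c('elephant','bear')",
    "filter_b": "behavior == 'attack' & tti == 'short' & threat %in% c('dog','human')",
    "description": "more shelter entries for fast feral than fast familiar threats"
  },
  {
    "hypothesis": "H5",
    "response": "escaped_to_shelter",
    "family": "binomial",
    "filter_a": "behavior == 'attack' & threat == 'rock'",
    "filter_b": "behavior == 'attack' & threat != 'rock'",
    "description": "fewer shelter entries for the ballistic rock"
  },
  {
    "hypothesis": "H6",
    "response": "escape_initiation_time",
    "family": "gaussian",
    "filter_a": "tti == 'long' & threat == 'rock'",
    "filter_b": "tti == 'long' & threat != 'rock'",
    "description": "latest initiation for the rock under long time-to-impact"
  },
  {
    "hypothesis": "H7",
    "response": "mean_speed",
    "family": "gaussian",
    "filter_a": "behavior == 'attack' & threat %in% c('elephant','bear','human','dog')",
    "filter_b": "behavior == 'attack' & threat %in% c('snake','spider')",
    "description": "faster escape from fast threats when attacked"
  },
  {
    "hypothesis": "H8",
    "response": "body_orient_escape",
    "family": "gaussian",
    "filter_a": "behavior == 'attack' & threat %in% c('snake','spider')",
    "filter_b": "behavior == 'attack' & threat %in% c('elephant','bear','human','dog')",
    "description": "body oriented more toward slow threats during escape"
  },
  {
    "hypothesis": "H9",
    "response": "head_orient_escape",
    "family": "gaussian",
    "filter_a": "tti == 'long'",
    "filter_b": "tti == 'short'",
    "description": "head oriented more toward the threat with more time"
  },
  {
    "hypothesis": "H10",
    "response": "mean_speed",
    "family": "gaussian",
    "filter_a": "tti == 'short'",
    "filter_b": "tti == 'long'",
    "description": "faster escape under short time-to-impact"
  },
  {
    "hypothesis": "H11",
    "response": "scan_appear",
    "family": "gaussian",
    "filter_a": "threat %in% c('elephant','bear','dog')",
    "filter_b": "threat == 'human'",
    "description": "less visual scanning after appearance of a human threat"
  }
]
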