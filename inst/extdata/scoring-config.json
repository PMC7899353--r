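{
 "notes": [
  "Tables marked provisional are defaults chosen to be monotone and range-correct;",
  "users holding the official protocol manual should override them via a user config file.",
  "Provisional/synthetic entries: pacer.conversion_15m, camsa.time_bins, steps bins and",
  "validity bounds, self_report map, csappa orientations, fill_in_the_blanks key."
 ],
 "pacer": {
  "laps_per_point": 5,
  "max_score": 10,
  "valid_lap_range": [
   1,
   229
  ],
  "conversion_15m": {
   "laps_15m": [
    1,
    2,
    3,
    4,
    5,
    6,
    7,
    8,
    9,
    10,
    11,
    12,
    13,
    14,
    15,
    16,
    17,
    18,
    19,
    20,
    21,
    22,
    23,
    24,
    25,
    26,
    27,
    28,
    29,
    30,
    31,
    32,
    33,
    34,
    35,
    36,
    37,
    38,
    39,
    40,
    41,
    42,
    43,
    44,
    45,
    46,
    47,
    48,
    49,
    50,
    51,
    52,
    53,
    54,
    55,
    56,
    57,
    58,
    59,
    60,
    61,
    62,
    63,
    64,
    65,
    66,
    67,
    68,
    69,
    70,
    71,
    72,
    73,
    74,
    75,
    76,
    77,
    78,
    79,
    80,
    81,
    82,
    83,
    84,
    85,
    86,
    87,
    88,
    89,
    90,
    91,
    92,
    93,
    94,
    95,
    96,
    97,
    98,
    99,
    100,
    101,
    102,
    103,
    104,
    105,
    106,
    107,
    108,
    109,
    110,
    111,
    112,
    113,
    114,
    115,
    116,
    117,
    118,
    119,
    120,
    121,
    122,
    123,
    124,
    125,
    126,
    127,
    128,
    129,
    130,
    131,
    132,
    133,
    134,
    135,
    136,
    137,
    138,
    139,
    140,
    141,
    142,
    143,
    144,
    145,
    146,
    147,
    148,
    149,
    150,
    151,
    152,
    153,
    154,
    155,
    156,
    157,
    158,
    159,
    160,
    161,
    162,
    163,
    164,
    165,
    166,
    167,
    168,
    169,
    170,
    171,
    172,
    173,
    174,
    175,
    176,
    177,
    178,
    179,
    180,
    181,
    182,
    183,
    184,
    185,
    186,
    187,
    188,
    189,
    190,
    191,
    192,
    193,
    194,
    195,
    196,
    197,
    198,
    199,
    200,
    201,
    202,
    203,
    204,
    205,
    206,
    207,
    208,
    209,
    210,
    211,
    212,
    213,
    214,
    215,
    216,
    217,
    218,
    219,
    220,
    221,
    222,
    223,
    224,
    225,
    226,
    227,
    228,
    229,
    230,
    231,
    232,
    233,
    234,
    235,
    236,
    237,
    238,
    239,
    240,
    241,
    242,
    243,
    244,
    245,
    246,
    247,
    248,
    249,
    250,
    251,
    252,
    253,
    254,
    255,
    256,
    257,
    258,
    259,
    260,
    261,
    262,
    263,
    264,
    265,
    266,
    267,
    268,
    269,
    270,
    271,
    272,
    273,
    274,
    275,
    276,
    277,
    278,
    279,
    280,
    281,
    282,
    283,
    284,
    285,
    286,
    287,
    288,
    289,
    290,
    291,
    292,
    293,
    294,
    295,
    296,
    297,
    298,
    299,
    300
   ],
   "laps_20m": [
    1,
    1,
    2,
    3,
    3,
    4,
    5,
    6,
    6,
    7,
    8,
    9,
    9,
    10,
    11,
    12,
    12,
    13,
    14,
    15,
    15,
    16,
    17,
    18,
    18,
    19,
    20,
    21,
    21,
    22,
    23,
    24,
    24,
    25,
    26,
    27,
    27,
    28,
    29,
    30,
    30,
    31,
    32,
    33,
    33,
    34,
    35,
    36,
    36,
    37,
    38,
    39,
    39,
    40,
    41,
    42,
    42,
    43,
    44,
    45,
    45,
    46,
    47,
    48,
    48,
    49,
    50,
    51,
    51,
    52,
    53,
    54,
    54,
    55,
    56,
    57,
    57,
    58,
    59,
    60,
    60,
    61,
    62,
    63,
    63,
    64,
    65,
    66,
    66,
    67,
    68,
    69,
    69,
    70,
    71,
    72,
    72,
    73,
    74,
    75,
    75,
    76,
    77,
    78,
    78,
    79,
    80,
    81,
    81,
    82,
    83,
    84,
    84,
    85,
    86,
    87,
    87,
    88,
    89,
    90,
    90,
    91,
    92,
    93,
    93,
    94,
    95,
    96,
    96,
    97,
    98,
    99,
    99,
    100,
    101,
    102,
    102,
    103,
    104,
    105,
    105,
    106,
    107,
    108,
    108,
    109,
    110,
    111,
    111,
    112,
    113,
    114,
    114,
    115,
    116,
    117,
    117,
    118,
    119,
    120,
    120,
    121,
    122,
    123,
    123,
    124,
    125,
    126,
    126,
    127,
    128,
    129,
    129,
    130,
    131,
    132,
    132,
    133,
    134,
    135,
    135,
    136,
    137,
    138,
    138,
    139,
    140,
    141,
    141,
    142,
    143,
    144,
    144,
    145,
    146,
    147,
    147,
    148,
    149,
    150,
    150,
    151,
    152,
    153,
    153,
    154,
    155,
    156,
    156,
    157,
    158,
    159,
    159,
    160,
    161,
    162,
    162,
    163,
    164,
    165,
    165,
    166,
    167,
    168,
    168,
    169,
    170,
    171,
    171,
    172,
    173,
    174,
    174,
    175,
    176,
    177,
    177,
    178,
    179,
    180,
    180,
    181,
    182,
    183,
    183,
    184,
    185,
    186,
    186,
    187,
    188,
    189,
    189,
    190,
    191,
    192,
    192,
    193,
    194,
    195,
    195,
    196,
    197,
    198,
    198,
    199,
    200,
    201,
    201,
    202,
    203,
    204,
    204,
    205,
    206,
    207,
    207,
    208,
    209,
    210,
    210,
    211,
    212,
    213,
    213,
    214,
    215,
    216,
    216,
    217,
    218,
    219,
    219,
    220,
    221,
    222,
    222,
    223,
    224,
    225
   ]
  }
 },
 "plank": {
  "seconds_per_point": 12,
  "max_score": 10
 },
 "camsa": {
  "min_seconds": 1,
  "time_bins": {
   "upper_seconds": [
    14,
    16,
    18,
    20,
    22,
    24,
    26,
    28,
    30,
    32,
    34,
    36,
    38
   ],
   "points": [
    14,
    13,
    12,
    11,
    10,
    9,
    8,
    7,
    6,
    5,
    4,
    3,
    2
   ],
   "slower_points": 1
  },
  "divisor": 2.8
 },
 "steps": {
  "min_daily_steps": 1000,
  "max_daily_steps": 30000,
  "min_wear_hours": 10.0,
  "bins_lower": [
   3000,
   3625,
   4250,
   4875,
   5500,
   6125,
   6750,
   7375,
   8000,
   8625,
   9250,
   9875,
   10500,
   11125,
   11750,
   12375,
   13000,
   13625,
   14250,
   14875,
   15500,
   16125,
   16750,
   17375,
   18000
  ]
 },
 "self_report": {
  "map": [
   0,
   1,
   2,
   3,
   4,
   5,
   5,
   5
  ]
 },
 "csappa": {
  "points": [
   0.6,
   1.2,
   1.8,
   2.5
  ],
  "reversed_items": [
   "csappa3",
   "csappa4"
  ],
  "subscales": {
   "predilection": [
    "csappa1",
    "csappa3",
    "csappa5"
   ],
   "adequacy": [
    "csappa2",
    "csappa4",
    "csappa6"
   ]
  }
 },
 "breq": {
  "divisor": 2
 },
 "answer_keys": {
  "pa_guideline": [
   3,
   "60 minutes or 1 hour"
  ],
  "crf_means": [
   2,
   "How well the heart can pump blood and the lungs can provide oxygen"
  ],
  "ms_means": [
   1,
   "How well the muscles can push, pull or stretch"
  ],
  "sports_skill": [
   4,
   "Watch a video, take a lesson or have a coach teach you how to kick and catch"
  ]
 },
 "fill_in_the_blanks": {
  "pa_is": [
   "fun"
  ],
  "pa_is_also": [
   "good for you"
  ],
  "improve": [
   "fitness"
  ],
  "increase": [
   "strength"
  ],
  "when_cooling_down": [
   "stretch"
  ],
  "heart_rate": [
   "decreases",
   "slows down"
  ]
 },
 "case_insensitive_matching": false,
 "interpretation_inputs": {
  "pacer": "pacer_score",
  "plank": "plank_time",
  "camsa": "camsa_score",
  "steps": "step_score",
  "pc": "pc_score",
  "db": "db_score",
  "mc": "mc_score",
  "ku": "ku_score",
  "capl": "capl_score"
 }
}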