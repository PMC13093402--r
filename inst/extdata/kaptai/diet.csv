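"prey","Sheatfish","Snakehead","Catfish","Knifefish","Spiny eel","Glassfish","Carp","Cichlid","Clupeid","Minnow","Whisker Shrimp","Insects/larvae","Zooplankton","Phytoplankton","Detritus"
"Sheatfish",0,0.002,0.001,0,0,0,0,0,0,0,0,0,0,0,0
"Snakehead",0,0,0.026,0,0,0,0,0,0,0,0,0,0,0,0
"Catfish",0.093,0.024,0.02,0,0,0,0,0,0,0,0,0,0,0,0
"Knifefish",0,0,0.003,0,0,0,0,0,0,0,0,0,0,0,0
"Spiny eel",0,0.005,3e-04,0,0,0,0,0,0,0,0,0,0,0,0
"Glassfish",0.093,0.026,0.002,0.037,0.093,0,0,0,0,0,0,0,0,0,0
"Carp",0.072,0,0.01,0,0,0,0,0,0,0,0,0,0,0,0
"Cichlid",0.031,0,0.002,0,0,0,0,0,0,0,0,0,0,0,0
"Clupeid",0.155,0.243,0.64,0.309,0.229,0.055,0,0,0,0,0,0,0,0,0
"Minnow",0.186,0.213,0.013,0.1,0.206,0,0,0,0,0,0,0,0,0,0
"Whisker Shrimp",0.175,0.1,0.005,0.013,0.05,0.035,0,0,0,0,0.011,0,0,0,0
"Insects/larvae",0,0.196,0.131,0.278,0.286,0.504,0.075,0.05,0.1,0,0.208,0,0,0,0
"Zooplankton",0,0.097,0.061,0.139,0.023,0.329,0.055,0.246,0.425,0.13,0.208,0.125,0.05,0,0
"Phytoplankton",0.082,0.041,0.044,0.077,0.069,0.044,0.52,0.7,0.375,0.85,0.104,0.305,0.8,0,0
"Detritus",0.113,0.052,0.044,0.046,0.046,0.033,0.35,0.004,0.1,0.02,0.469,0.57,0.15,0,0
"Import",0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
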