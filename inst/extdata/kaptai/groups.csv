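"name","type","biomass","pb","qb","ee","landings","unassim","ba","migration"
"Sheatfish","consumer",0.012,2.8,10.9,NA,0.0130343053173242,0.2,0,0
"Snakehead","consumer",NA,2.27,8.93,0.95,0.0393842195540309,0.2,0,0
"Catfish","consumer",0.368,2.78,12.12,NA,0.600814751286449,0.2,0,0
"Knifefish","consumer",0.091,1.12,7.4,NA,0.0308987993138937,0.2,0,0
"Spiny eel","consumer",0.035,0.75,9.5,NA,0.0152332761578045,0.2,0,0
"Glassfish","consumer",0.066,3.11,23.3,NA,0.0979931389365352,0.2,0,0
"Carp","consumer",0.055,2.29,19.14,NA,0.070917667238422,0.2,0,0
"Cichlid","consumer",0.017,1.39,14.1,NA,0.0104219554030875,0.2,0,0
"Clupeid","consumer",3.264,6.29,35.3,NA,9.15598627787307,0.2,0,0
"Minnow","consumer",0.302,3.26,76.2,NA,0.616181818181818,0.2,0,0
"Whisker Shrimp","consumer",0.135,3.16,12.64,NA,0.211428515074542,0.2,0,0
"Insects/larvae","consumer",4.125,4,30,NA,0,0.2,0,0
"Zooplankton","consumer",12.85,35,140,NA,0,0.2,0,0
"Phytoplankton","producer",11.7,203,NA,NA,0,0,0,0
"Detritus","detritus",1,NA,NA,NA,0,0,0,0
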