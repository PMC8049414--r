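# Cardinal temperature limits (degrees C) for phenological development,
# compiled from the crop ecophysiology literature.
- species: maize
  Tbase1: 8.0
  Topt1: 30.0
  Topt2: 37.0
  Tbase2: 45.0
- species: wheat
  Tbase1: 0.0
  Topt1: 25.0
  Topt2: 28.0
  Tbase2: 40.0
- species: rainfed_rice
  Tbase1: 8.0
  Topt1: 30.0
  Topt2: 37.0
  Tbase2: 45.0
- species: irrigated_rice_vegetative
  Tbase1: 8.0
  Topt1: 28.0
  Topt2: 40.0
  Tbase2: 45.0
- species: irrigated_rice_reproductive
  Tbase1: 15.0
  Topt1: 25.0
  Topt2: 35.0
  Tbase2: 45.0
- species: sorghum
  Tbase1: 8.0
  Topt1: 30.0
  Topt2: 37.0
  Tbase2: 45.0
- species: soybean
  Tbase1: 8.0
  Topt1: 30.0
  Topt2: 35.0
  Tbase2: 45.0
- species: peanut
  Tbase1: 8.0
  Topt1: 30.0
  Topt2: 35.0
  Tbase2: 45.0
- species: canola
  Tbase1: 0.0
  Topt1: 25.0
  Topt2: 28.0
  Tbase2: 40.0
- species: sunflower
  Tbase1: 8.0
  Topt1: 30.0
  Topt2: 34.0
  Tbase2: 45.0
- species: dry_bean
  Tbase1: 8.0
  Topt1: 30.0
  Topt2: 35.0
  Tbase2: 45.0
- species: chickpea
  Tbase1: 0.0
  Topt1: 25.0
  Topt2: 30.0
  Tbase2: 40.0
- species: barley
  Tbase1: 0.0
  Topt1: 25.0
  Topt2: 28.0
  Tbase2: 40.0
- species: sugarcane
  Tbase1: 5.0
  Topt1: 22.5
  Topt2: 35.0
  Tbase2: 40.0
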