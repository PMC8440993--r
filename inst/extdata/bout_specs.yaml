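# Per-individual dive-bout summary statistics for six leatherback (Dc),
# three loggerhead (Cc) and four green (Cm) turtles: proportion of dives (%),
# dive duration (s, mean/sd) and maximum dive depth (m, mean/sd) per depth
# bin (shallow < 30 m, medium 30-90 m, deep > 90 m).  Bins the animal never
# used carry proportion 0.  Consumed by referenceBoutSpecs().
Dc1:
  species: leatherback
  body_mass: 334
  shallow: {proportion: 87.2, duration_mean: 209, duration_sd: 251, depth_mean: 6.3, depth_sd: 7.0}
  medium:  {proportion: 11.6, duration_mean: 827, duration_sd: 157, depth_mean: 49.1, depth_sd: 14.4}
  deep:    {proportion: 1.2, duration_mean: 839, duration_sd: 97, depth_mean: 108.7, depth_sd: 15.3}
Dc2:
  species: leatherback
  body_mass: 356
  shallow: {proportion: 90.3, duration_mean: 177, duration_sd: 222, depth_mean: 4.1, depth_sd: 5.3}
  medium:  {proportion: 6.5, duration_mean: 1155, duration_sd: 248, depth_mean: 55.5, depth_sd: 18.6}
  deep:    {proportion: 3.2, duration_mean: 1345, duration_sd: 141, depth_mean: 136.4, depth_sd: 88.3}
Dc3:
  species: leatherback
  body_mass: 392
  shallow: {proportion: 84.0, duration_mean: 74, duration_sd: 138, depth_mean: 9.5, depth_sd: 7.0}
  medium:  {proportion: 14.2, duration_mean: 244, duration_sd: 349, depth_mean: 51.3, depth_sd: 15.8}
  deep:    {proportion: 1.9, duration_mean: 367, duration_sd: 473, depth_mean: 134.1, depth_sd: 67.8}
Dc4:
  species: leatherback
  body_mass: 217
  shallow: {proportion: 75.0, duration_mean: 175, duration_sd: 162, depth_mean: 7.8, depth_sd: 8.0}
  medium:  {proportion: 23.2, duration_mean: 581, duration_sd: 161, depth_mean: 48.2, depth_sd: 13.8}
  deep:    {proportion: 1.8, duration_mean: 812, duration_sd: 133, depth_mean: 120.7, depth_sd: 36.9}
Dc5:
  species: leatherback
  body_mass: 371
  shallow: {proportion: 71.7, duration_mean: 230, duration_sd: 231, depth_mean: 9.3, depth_sd: 9.4}
  medium:  {proportion: 25.0, duration_mean: 775, duration_sd: 234, depth_mean: 49.5, depth_sd: 15.2}
  deep:    {proportion: 3.2, duration_mean: 1166, duration_sd: 211, depth_mean: 114.3, depth_sd: 20.0}
Dc6:
  species: leatherback
  body_mass: 360
  shallow: {proportion: 92.8, duration_mean: 156, duration_sd: 174, depth_mean: 4.3, depth_sd: 5.5}
  medium:  {proportion: 6.2, duration_mean: 911, duration_sd: 199, depth_mean: 54.9, depth_sd: 15.9}
  deep:    {proportion: 0.9, duration_mean: 1063, duration_sd: 98, depth_mean: 115.9, depth_sd: 38.7}
Cc1:
  species: loggerhead
  body_mass: 44
  shallow: {proportion: 97.3, duration_mean: 150, duration_sd: 499, depth_mean: 0.7, depth_sd: 1.9}
  medium:  {proportion: 2.7, duration_mean: 1396, duration_sd: 604, depth_mean: 44.6, depth_sd: 6.5}
  deep:    {proportion: 0.0, duration_mean: 0, duration_sd: 0, depth_mean: 0, depth_sd: 0}
Cc2:
  species: loggerhead
  body_mass: 89
  shallow: {proportion: 94.2, duration_mean: 181, duration_sd: 396, depth_mean: 1.1, depth_sd: 2.3}
  medium:  {proportion: 5.8, duration_mean: 1685, duration_sd: 840, depth_mean: 53.3, depth_sd: 7.5}
  deep:    {proportion: 0.0, duration_mean: 0, duration_sd: 0, depth_mean: 0, depth_sd: 0}
Cc3:
  species: loggerhead
  body_mass: 60
  shallow: {proportion: 93.9, duration_mean: 256, duration_sd: 544, depth_mean: 1.0, depth_sd: 2.1}
  medium:  {proportion: 6.1, duration_mean: 2117, duration_sd: 439, depth_mean: 66.3, depth_sd: 8.9}
  deep:    {proportion: 0.0, duration_mean: 0, duration_sd: 0, depth_mean: 0, depth_sd: 0}
Cm1:
  species: green
  body_mass: 71
  shallow: {proportion: 88.0, duration_mean: 183, duration_sd: 438, depth_mean: 2.3, depth_sd: 4.4}
  medium:  {proportion: 10.7, duration_mean: 2705, duration_sd: 1215, depth_mean: 58.1, depth_sd: 17.7}
  deep:    {proportion: 1.2, duration_mean: 3106, duration_sd: 891, depth_mean: 96.9, depth_sd: 6.5}
Cm2:
  species: green
  body_mass: 81
  shallow: {proportion: 96.1, duration_mean: 502, duration_sd: 542, depth_mean: 5.0, depth_sd: 5.1}
  medium:  {proportion: 3.9, duration_mean: 1314, duration_sd: 479, depth_mean: 48.4, depth_sd: 9.7}
  deep:    {proportion: 0.0, duration_mean: 0, duration_sd: 0, depth_mean: 0, depth_sd: 0}
Cm3:
  species: green
  body_mass: 65
  shallow: {proportion: 97.6, duration_mean: 324, duration_sd: 382, depth_mean: 4.6, depth_sd: 5.0}
  medium:  {proportion: 2.4, duration_mean: 892, duration_sd: 390, depth_mean: 44.2, depth_sd: 11.1}
  deep:    {proportion: 0.0, duration_mean: 944, duration_sd: 0, depth_mean: 90.5, depth_sd: 0}
Cm4:
  species: green
  body_mass: 70
  shallow: {proportion: 100.0, duration_mean: 431, duration_sd: 500, depth_mean: 2.4, depth_sd: 1.8}
  medium:  {proportion: 0.0, duration_mean: 0, duration_sd: 0, depth_mean: 0, depth_sd: 0}
  deep:    {proportion: 0.0, duration_mean: 0, duration_sd: 0, depth_mean: 0, depth_sd: 0}
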