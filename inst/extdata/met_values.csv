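# Curated MET lookup table: a small subset of common sports with separate
# youth (<18 y) and adult (18+ y) values, in the style of the standard
# youth and adult energy-expenditure compendia. Values are multiples of
# resting energy expenditure (~1 kcal/kg/h). User-extensible: supply a CSV
# with the same columns to load_met_table().
activity,met_youth,met_adult
soccer,8.0,7.0
field_hockey,8.0,8.0
basketball,7.0,6.5
volleyball,5.0,4.0
handball,8.0,8.0
korfball,7.0,6.5
tennis,6.5,7.3
squash,8.5,12.0
badminton,5.0,5.5
table_tennis,4.0,4.0
running,8.5,9.8
jogging,7.0,7.0
track_and_field,7.5,8.0
swimming,7.0,7.0
swimming_competitive,9.0,9.8
rowing,6.5,7.0
cycling_sport,7.5,8.0
mountain_biking,8.0,8.5
speed_skating,9.0,9.0
ice_skating,6.0,7.0
inline_skating,7.5,7.5
gymnastics,4.5,3.8
dance,5.5,5.0
ballet,5.0,5.0
aerobics,6.5,7.3
fitness_training,5.0,5.0
weight_training,4.0,3.5
judo,8.5,10.3
karate,8.5,10.3
boxing,9.0,9.0
horse_riding,4.5,5.5
golf,4.0,4.8
hiking_sport,6.0,6.0
climbing,7.0,8.0
water_polo,9.0,10.0
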