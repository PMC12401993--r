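pattern	category
# Ordered rules: the first pattern (case-insensitive regular expression)
# matching an element's function description (or its name, when PlantCARE
# reports no description) assigns the category. Edit freely or supply your
# own file to read_category_map().
core promoter element	Promoter core
common cis-acting element in promoter	Promoter core
TATA-box	Promoter core
CAAT-box	Promoter core
abscisic acid	Hormone responsiveness
MeJA	Hormone responsiveness
methyl jasmonate	Hormone responsiveness
salicylic acid	Hormone responsiveness
gibberellin	Hormone responsiveness
auxin	Hormone responsiveness
ethylene	Hormone responsiveness
defense and stress	Stress/defense responsiveness
defence and stress	Stress/defense responsiveness
low-temperature	Stress/defense responsiveness
drought	Stress/defense responsiveness
anaerobic	Stress/defense responsiveness
wound	Stress/defense responsiveness
stress respons	Stress/defense responsiveness
light respons	Light responsiveness
circadian	Light responsiveness
meristem	Growth & development
seed-specific	Growth & development
endosperm	Growth & development
zein metabolism	Growth & development
cell cycle	Growth & development
differentiation	Growth & development
development	Growth & development
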