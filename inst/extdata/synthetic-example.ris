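TY  - JOUR
TI  - Balance training to prevent falls in community-dwelling older adults
AU  - Example, Alice
AU  - Sample, Bob
PY  - 2018
JO  - Journal of Synthetic Examples
DO  - 10.9999/synthetic.0001
AB  - A fabricated trial abstract describing balance and strength training for falls prevention in older adults. Synthetic text for demonstration only.
ER  -
TY  - JOUR
TI  - Exercise interventions and fear of falling: a fabricated review
AU  - Sample, Bob
PY  - 2020
JO  - Journal of Synthetic Examples
AB  - Fabricated abstract on exercise programmes addressing fear of falling and activity avoidance. Synthetic text for demonstration only.
ER  -
TY  - JOUR
TI  - Soil microbiome diversity under crop rotation
AU  - Decoy, Carol
PY  - 2019
JO  - Unrelated Synthetic Journal
AB  - Fabricated abstract about agricultural soil microbiota, unrelated to falls. Synthetic text for demonstration only.
ER  -
TY  - JOUR
TI  - Balance training to prevent falls in community-dwelling older adults
AU  - Example, Alice
AU  - Sample, Bob
PY  - 2018
JO  - Journal of Synthetic Examples
AB  - A fabricated trial abstract describing balance and strength training for falls prevention in older adults. Synthetic text for demonstration only.
ER  -
TY  - JOUR
TI  - Vitamin D supplementation and falls risk: fabricated cohort data
AU  - Example, Alice
PY  - 2021
JO  - Journal of Synthetic Examples
AB  - Fabricated abstract linking vitamin D status to falls incidence in older adults. Synthetic text for demonstration only.
ER  -
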