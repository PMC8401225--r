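# Banded FVNL-percentage estimation rules, emulating manual dietitian
# scoring from the ingredient list. Negligible ingredients are dropped
# before ranking; the rank of the first FVNL ingredient selects the
# starting band; concentrated forms and low FVNL share each demote one band.
bands: [0, 25, 50, 75, 100]
rank_bands:
  - {max_rank: 1, band: 100}
  - {max_rank: 2, band: 75}
  - {max_rank: 3, band: 50}
  - {max_rank: 5, band: 25}
minority_share: 0.15
fvnl_terms:
  - fruit
  - apple
  - orange
  - mango
  - peach
  - pear
  - pineapple
  - grape
  - berry
  - strawberry
  - banana
  - apricot
  - guava
  - litchi
  - tomato
  - tomatoes
  - vegetable
  - vegetables
  - pea
  - peas
  - carrot
  - carrots
  - spinach
  - onion
  - onions
  - pumpkin
  - butternut
  - corn
  - sweetcorn
  - potato
  - beetroot
  - cabbage
  - pepper
  - peppers
  - mushroom
  - mushrooms
  - bean
  - beans
  - chickpea
  - chickpeas
  - lentil
  - lentils
  - legume
  - legumes
  - soya
  - soybean
  - peanut
  - peanuts
  - almond
  - almonds
  - cashew
  - cashews
  - nut
  - nuts
  - macadamia
  - pecan
  - walnut
concentrated_terms:
  - concentrate
  - concentrated
  - paste
  - powder
  - powdered
  - dried
  - dehydrated
  - puree
  - extract
negligible_terms:
  - water
  - salt
  - spice
  - spices
  - herbs
  - preservative
  - antioxidant
  - acidity regulator
  - citric acid
  - ascorbic acid
  - firming agent
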