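# Marker lists for the processing-level heuristic. Any group-4 marker in the
# ingredient text assigns ultra-processed (4); else any group-3 marker
# assigns processed (3); else unprocessed/minimally processed (1). Culinary
# ingredients (group 2) are omitted from supply summaries.
group4:
  - aspartame
  - acesulfame
  - sucralose
  - saccharin
  - cyclamate
  - stevia
  - maltitol
  - sorbitol
  - xylitol
  - flavouring
  - flavourant
  - flavour enhancer
  - emulsifier
  - stabiliser
  - stabilizer
  - thickener
  - colourant
  - modified starch
  - glucose syrup
  - high fructose corn syrup
  - invert sugar
  - maltodextrin
  - hydrogenated vegetable oil
  - soy protein isolate
  - whey protein isolate
  - monosodium glutamate
  - preservative
  - antioxidant
  - humectant
  - anti-caking agent
group3:
  - salt
  - sugar
  - vegetable oil
  - sunflower oil
  - olive oil
  - vinegar
  - brine
  - syrup
  - honey
  - butter
category_defaults: {}
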