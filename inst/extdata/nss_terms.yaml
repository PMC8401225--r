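# Non-sugar-sweetener search terms: canonical sweeteners with synonyms and
# additive codes (E950-E969 intense sweeteners; polyol E-codes). Compiled
# from standard additive nomenclature; a survey-specific list can replace
# this file verbatim.
version: 1
sweeteners:
  - canonical: aspartame
    class: intense
    synonyms: [e951, aspartame-acesulfame salt, e962]
  - canonical: acesulfame
    class: intense
    synonyms: [acesulfame k, acesulfame-k, acesulfame potassium, ace-k, e950]
  - canonical: sucralose
    class: intense
    synonyms: [e955]
  - canonical: saccharin
    class: intense
    synonyms: [e954, sodium saccharin, calcium saccharin]
  - canonical: cyclamate
    class: intense
    synonyms: [e952, sodium cyclamate, calcium cyclamate, cyclamic acid]
  - canonical: steviol glycosides
    class: intense
    synonyms: [stevia, steviol, rebaudioside, rebaudioside a, stevia extract, e960]
  - canonical: neotame
    class: intense
    synonyms: [e961]
  - canonical: advantame
    class: intense
    synonyms: [e969]
  - canonical: thaumatin
    class: intense
    synonyms: [e957]
  - canonical: neohesperidin dc
    class: intense
    synonyms: [neohesperidin dihydrochalcone, neohesperidine dc, e959]
  - canonical: sorbitol
    class: polyol
    synonyms: [e420, sorbitol syrup]
  - canonical: mannitol
    class: polyol
    synonyms: [e421]
  - canonical: isomalt
    class: polyol
    synonyms: [e953]
  - canonical: maltitol
    class: polyol
    synonyms: [e965, maltitol syrup]
  - canonical: lactitol
    class: polyol
    synonyms: [e966]
  - canonical: xylitol
    class: polyol
    synonyms: [e967]
  - canonical: erythritol
    class: polyol
    synonyms: [e968]
  - canonical: polyglycitol
    class: polyol
    synonyms: [e964, polyglycitol syrup, hydrogenated starch hydrolysate]
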