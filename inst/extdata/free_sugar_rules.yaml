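# Category rules for estimating free sugar from declared total sugar when
# free sugar is not declared. "all_free": all sugar counts as free (fully
# formulated products; juice sugars count as free under the WHO definition).
# "none_free": sugar is intrinsic (lactose in plain dairy, sugar inside
# intact plant tissue). "fraction": a fixed share is free (mixed products).
# Survey-specific rule tables can replace these defaults.
breakfast cereals:          {type: all_free}
cereals & cereal products:  {type: all_free}
confectionery & dessert:    {type: all_free}
dairy:                      {type: none_free}
fruits & vegetables:        {type: none_free}
vegetables:                 {type: none_free}
legumes:                    {type: none_free}
mixed dishes:               {type: all_free}
protein:                    {type: all_free}
snack foods:                {type: all_free}
soups & sauces:             {type: all_free}
fats & oils:                {type: all_free}
dairy drinks:               {type: fraction, fraction: 0.8}
other beverages:            {type: all_free}
sodas:                      {type: all_free}
100% fruit juice:           {type: all_free}
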