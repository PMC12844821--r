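category,n_products,n_generic_names,n_in_ge3,capacity_pct,reduction_pct
Fat or fat product,4,2,3,75,50
Grain or grain product,11,4,8,72.7,63.6
"Milk, milk product or milk substitute",13,5,10,76.9,61.5
Vegetable or vegetable product,6,3,3,50,50
Overall,34,14,24,70.6,58.8
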