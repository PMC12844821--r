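category,n_products,n_generic_names,names_1,names_2,names_ge3
Fat or fat product,4,2,1,0,1
Grain or grain product,11,4,1,1,2
"Milk, milk product or milk substitute",13,5,1,1,3
Vegetable or vegetable product,6,3,1,1,1
Total,34,14,4,3,7
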