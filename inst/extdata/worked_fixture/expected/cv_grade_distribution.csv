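nutrient,grade,count,pct
energy,lt20,7,100
energy,between20and40,0,0
energy,ge40,0,0
energy,undefined,0,0
protein,lt20,7,100
protein,between20and40,0,0
protein,ge40,0,0
protein,undefined,0,0
total_fat,lt20,7,100
total_fat,between20and40,0,0
total_fat,ge40,0,0
total_fat,undefined,0,0
sfa,lt20,7,100
sfa,between20and40,0,0
sfa,ge40,0,0
sfa,undefined,0,0
carbohydrate,lt20,7,100
carbohydrate,between20and40,0,0
carbohydrate,ge40,0,0
carbohydrate,undefined,0,0
total_sugars,lt20,6,85.7
total_sugars,between20and40,0,0
total_sugars,ge40,1,14.3
total_sugars,undefined,0,0
sodium,lt20,7,100
sodium,between20and40,0,0
sodium,ge40,0,0
sodium,undefined,0,0
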