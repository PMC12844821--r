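nutrient,category,count
energy,Fat or fat product,0
energy,Grain or grain product,0
energy,"Milk, milk product or milk substitute",0
energy,Vegetable or vegetable product,0
protein,Fat or fat product,0
protein,Grain or grain product,0
protein,"Milk, milk product or milk substitute",0
protein,Vegetable or vegetable product,0
total_fat,Fat or fat product,0
total_fat,Grain or grain product,0
total_fat,"Milk, milk product or milk substitute",0
total_fat,Vegetable or vegetable product,0
sfa,Fat or fat product,0
sfa,Grain or grain product,0
sfa,"Milk, milk product or milk substitute",0
sfa,Vegetable or vegetable product,0
carbohydrate,Fat or fat product,0
carbohydrate,Grain or grain product,0
carbohydrate,"Milk, milk product or milk substitute",0
carbohydrate,Vegetable or vegetable product,0
total_sugars,Fat or fat product,0
total_sugars,Grain or grain product,1
total_sugars,"Milk, milk product or milk substitute",0
total_sugars,Vegetable or vegetable product,0
sodium,Fat or fat product,0
sodium,Grain or grain product,0
sodium,"Milk, milk product or milk substitute",0
sodium,Vegetable or vegetable product,0
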