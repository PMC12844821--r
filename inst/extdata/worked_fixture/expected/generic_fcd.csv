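generic_name,category,subcategory,group,subgroup,basis,n,n_complete,provenance,inherent_heterogeneity,member_ids,descriptors,energy_mean,energy_sd,energy_cv,energy_grade,protein_mean,protein_sd,protein_cv,protein_grade,total_fat_mean,total_fat_sd,total_fat_cv,total_fat_grade,sfa_mean,sfa_sd,sfa_cv,sfa_grade,carbohydrate_mean,carbohydrate_sd,carbohydrate_cv,carbohydrate_grade,total_sugars_mean,total_sugars_sd,total_sugars_cv,total_sugars_grade,sodium_mean,sodium_sd,sodium_cv,sodium_grade,fiber_mean,fiber_sd,fiber_cv,fiber_grade,polyols_mean,polyols_sd,polyols_cv,polyols_grade
"Butter, cow, solid, salted",Fat or fat product,Animal fats,Butters,Butter,per_100g,1,NA,step1,FALSE,WF028,source=cow; form=solid; salting=salted,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
"Margarine, sunflower, spreadable, unsalted",Fat or fat product,Vegetable fats,Margarines,Margarine,per_100g,3,3,step1,FALSE,WF025;WF026;WF027,source=sunflower; form=spreadable; salting=unsalted,542.8,9,0.01658069270449521,lt20,0.2,0,0,lt20,60,1,0.016666666666666666,lt20,15,0.1999999999999993,0.013333333333333286,lt20,0.5,0,0,lt20,0.2,0,0,lt20,30,1,0.03333333333333333,lt20,0,0,0,NA,0,0,0,NA
"Bread, multigrain, wholegrain, sliced",Grain or grain product,Breads,Leavened breads,Bread,per_100g,5,5,step1,FALSE,WF014;WF015;WF016;WF017;WF018,main_grain=multigrain; processing=wholegrain; form=sliced,260,4.503887209955407,0.0173226431152131,lt20,9,0.1581138830084184,0.017568209223157598,lt20,4,0.07071067811865465,0.017677669529663664,lt20,1.2,0,0,lt20,45,0.7905694150420949,0.017568209223157664,lt20,3.6,0.07071067811865482,0.019641855032959673,lt20,450,3.5355339059327378,0.007856742013183862,lt20,4,0.07071067811865465,0.017677669529663664,NA,0,0,0,NA
"Bread, rye, loaf",Grain or grain product,Breads,Leavened breads,Bread,per_100g,1,NA,step1,FALSE,WF022,main_grain=rye; form=loaf,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
"Bread, wheat, wholegrain, rusks",Grain or grain product,Breads,Leavened breads,Bread,per_100g,2,NA,step1,FALSE,WF023;WF024,main_grain=wheat; processing=wholegrain; form=rusks,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
"Biscuits, wheat, plain",Grain or grain product,Fine bakery wares,Biscuits,Biscuits,per_100g,3,3,step1,TRUE,WF019;WF020;WF021,main_grain=wheat; coating_or_filling=plain,444,5.7999999999999545,0.01306306306306296,lt20,7,0,0,lt20,18,0.1999999999999993,0.011111111111111072,lt20,9,0,0,lt20,62,1,0.016129032258064516,lt20,25,15,0.6,ge40,350,0,0,lt20,3,0,0,NA,0,0,0,NA
"Yogurt, cow, strained, 0% fat, plain","Milk, milk product or milk substitute",Dairy products,Fermented milks,Yogurt,per_100g,4,4,step1,FALSE,WF001;WF002;WF003;WF004,animal_of_origin=cow; processing=strained; fat_content=0% fat; flavor=plain,57.8,0.9797958971132678,0.016951486109226088,lt20,10,0.16329931618554464,0.016329931618554464,lt20,0.2,0,0,lt20,0.1,0,0,lt20,4,0.0816496580927725,0.020412414523193124,lt20,4,0.0816496580927725,0.020412414523193124,lt20,50,1.632993161855452,0.03265986323710904,lt20,0,0,0,NA,0,0,0,NA
"Yogurt, goat, plain","Milk, milk product or milk substitute",Dairy products,Fermented milks,Yogurt,per_100g,2,NA,step1,FALSE,WF012;WF013,animal_of_origin=goat; flavor=plain,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
"Yogurt, sheep, plain","Milk, milk product or milk substitute",Dairy products,Fermented milks,Yogurt,per_100g,1,NA,step1,FALSE,WF011,animal_of_origin=sheep; flavor=plain,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
"Milk, cow, pasteurized, full fat, chocolate, with sugar","Milk, milk product or milk substitute",Milks,Liquid milks,Milk,per_100mL,3,3,step3_refined,FALSE,WF005;WF006;WF007,animal_of_origin=cow; processing=pasteurized; fat_content=full fat; flavor=chocolate; sweetener=with sugar,96.7,3.3000000000000043,0.03412616339193386,lt20,3.3,0.09999999999999987,0.030303030303030266,lt20,3.5,0.10000000000000009,0.0285714285714286,lt20,2.2,0.09999999999999987,0.04545454545454539,lt20,13,0.5,0.038461538461538464,lt20,12,0.5,0.041666666666666664,lt20,45,1,0.022222222222222223,lt20,0,0,0,NA,0,0,0,NA
"Milk, cow, pasteurized, full fat, chocolate, with sweeteners","Milk, milk product or milk substitute",Milks,Liquid milks,Milk,per_100mL,3,3,step3_refined,FALSE,WF008;WF009;WF010,animal_of_origin=cow; processing=pasteurized; fat_content=full fat; flavor=chocolate; sweetener=with sweeteners,64.7,2.1000000000000014,0.032457496136012384,lt20,3.3,0.09999999999999987,0.030303030303030266,lt20,3.5,0.10000000000000009,0.0285714285714286,lt20,2.2,0.09999999999999987,0.04545454545454539,lt20,5,0.20000000000000018,0.040000000000000036,lt20,4,0.20000000000000018,0.050000000000000044,lt20,45,1,0.022222222222222223,lt20,0,0,0,NA,0,0,0,NA
"Asparagus, canned, in brine",Vegetable or vegetable product,Canned vegetables,Canned stem vegetables,Asparagus,per_100g,2,NA,step1,FALSE,WF032;WF033,processing=canned; liquid_matrix=in brine,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
"Asparagus, canned, in water",Vegetable or vegetable product,Canned vegetables,Canned stem vegetables,Asparagus,per_100g,1,NA,step1,FALSE,WF034,processing=canned; liquid_matrix=in water,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA,NA
"Spinach, frozen",Vegetable or vegetable product,Frozen vegetables,Frozen leaf vegetables,Spinach,per_100g,3,3,step1,FALSE,WF029;WF030;WF031,processing=frozen,26.8,0.8000000000000007,0.029850746268656744,lt20,2.9,0.10000000000000009,0.03448275862068969,lt20,0.4,0,0,lt20,0.1,0,0,lt20,1.8,0.09999999999999998,0.05555555555555554,lt20,0.7,0.10000000000000003,0.1428571428571429,lt20,80,2,0.025,lt20,2.2,0,0,NA,0,0,0,NA
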