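generic_name,category,subcategory,group,subgroup,basis,descriptors,member_ids,n,provenance,inherent_heterogeneity
"Butter, cow, solid, salted",Fat or fat product,Animal fats,Butters,Butter,per_100g,source=cow; form=solid; salting=salted,WF028,1,step1,FALSE
"Margarine, sunflower, spreadable, unsalted",Fat or fat product,Vegetable fats,Margarines,Margarine,per_100g,source=sunflower; form=spreadable; salting=unsalted,WF025;WF026;WF027,3,step1,FALSE
"Bread, multigrain, wholegrain, sliced",Grain or grain product,Breads,Leavened breads,Bread,per_100g,main_grain=multigrain; processing=wholegrain; form=sliced,WF014;WF015;WF016;WF017;WF018,5,step1,FALSE
"Bread, rye, loaf",Grain or grain product,Breads,Leavened breads,Bread,per_100g,main_grain=rye; form=loaf,WF022,1,step1,FALSE
"Bread, wheat, wholegrain, rusks",Grain or grain product,Breads,Leavened breads,Bread,per_100g,main_grain=wheat; processing=wholegrain; form=rusks,WF023;WF024,2,step1,FALSE
"Biscuits, wheat, plain",Grain or grain product,Fine bakery wares,Biscuits,Biscuits,per_100g,main_grain=wheat; coating_or_filling=plain,WF019;WF020;WF021,3,step1,TRUE
"Yogurt, cow, strained, 0% fat, plain","Milk, milk product or milk substitute",Dairy products,Fermented milks,Yogurt,per_100g,animal_of_origin=cow; processing=strained; fat_content=0% fat; flavor=plain,WF001;WF002;WF003;WF004,4,step1,FALSE
"Yogurt, goat, plain","Milk, milk product or milk substitute",Dairy products,Fermented milks,Yogurt,per_100g,animal_of_origin=goat; flavor=plain,WF012;WF013,2,step1,FALSE
"Yogurt, sheep, plain","Milk, milk product or milk substitute",Dairy products,Fermented milks,Yogurt,per_100g,animal_of_origin=sheep; flavor=plain,WF011,1,step1,FALSE
"Milk, cow, pasteurized, full fat, chocolate, with sugar","Milk, milk product or milk substitute",Milks,Liquid milks,Milk,per_100mL,animal_of_origin=cow; processing=pasteurized; fat_content=full fat; flavor=chocolate; sweetener=with sugar,WF005;WF006;WF007,3,step3_refined,FALSE
"Milk, cow, pasteurized, full fat, chocolate, with sweeteners","Milk, milk product or milk substitute",Milks,Liquid milks,Milk,per_100mL,animal_of_origin=cow; processing=pasteurized; fat_content=full fat; flavor=chocolate; sweetener=with sweeteners,WF008;WF009;WF010,3,step3_refined,FALSE
"Asparagus, canned, in brine",Vegetable or vegetable product,Canned vegetables,Canned stem vegetables,Asparagus,per_100g,processing=canned; liquid_matrix=in brine,WF032;WF033,2,step1,FALSE
"Asparagus, canned, in water",Vegetable or vegetable product,Canned vegetables,Canned stem vegetables,Asparagus,per_100g,processing=canned; liquid_matrix=in water,WF034,1,step1,FALSE
"Spinach, frozen",Vegetable or vegetable product,Frozen vegetables,Frozen leaf vegetables,Spinach,per_100g,processing=frozen,WF029;WF030;WF031,3,step1,FALSE
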