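product_id,long_name,category,subcategory,group,subgroup,basis
WF001,Yogurt cow strained 0% fat plain brand 1,"Milk, milk product or milk substitute",Dairy products,Fermented milks,Yogurt,per_100g
WF002,Yogurt cow strained 0% fat plain brand 2,"Milk, milk product or milk substitute",Dairy products,Fermented milks,Yogurt,per_100g
WF003,Yogurt cow strained 0% fat plain brand 3,"Milk, milk product or milk substitute",Dairy products,Fermented milks,Yogurt,per_100g
WF004,Yogurt cow strained 0% fat plain brand 4,"Milk, milk product or milk substitute",Dairy products,Fermented milks,Yogurt,per_100g
WF005,Milk cow pasteurized full fat chocolate brand 5,"Milk, milk product or milk substitute",Milks,Liquid milks,Milk,per_100mL
WF006,Milk cow pasteurized full fat chocolate brand 6,"Milk, milk product or milk substitute",Milks,Liquid milks,Milk,per_100mL
WF007,Milk cow pasteurized full fat chocolate brand 7,"Milk, milk product or milk substitute",Milks,Liquid milks,Milk,per_100mL
WF008,Milk cow pasteurized full fat chocolate brand 8,"Milk, milk product or milk substitute",Milks,Liquid milks,Milk,per_100mL
WF009,Milk cow pasteurized full fat chocolate brand 9,"Milk, milk product or milk substitute",Milks,Liquid milks,Milk,per_100mL
WF010,Milk cow pasteurized full fat chocolate brand 10,"Milk, milk product or milk substitute",Milks,Liquid milks,Milk,per_100mL
WF011,Yogurt sheep plain brand 11,"Milk, milk product or milk substitute",Dairy products,Fermented milks,Yogurt,per_100g
WF012,Yogurt goat plain brand 12,"Milk, milk product or milk substitute",Dairy products,Fermented milks,Yogurt,per_100g
WF013,Yogurt goat plain brand 13,"Milk, milk product or milk substitute",Dairy products,Fermented milks,Yogurt,per_100g
WF014,Bread multigrain wholegrain sliced brand 14,Grain or grain product,Breads,Leavened breads,Bread,per_100g
WF015,Bread multigrain wholegrain sliced brand 15,Grain or grain product,Breads,Leavened breads,Bread,per_100g
WF016,Bread multigrain wholegrain sliced brand 16,Grain or grain product,Breads,Leavened breads,Bread,per_100g
WF017,Bread multigrain wholegrain sliced brand 17,Grain or grain product,Breads,Leavened breads,Bread,per_100g
WF018,Bread multigrain wholegrain sliced brand 18,Grain or grain product,Breads,Leavened breads,Bread,per_100g
WF019,Biscuits wheat plain brand 19,Grain or grain product,Fine bakery wares,Biscuits,Biscuits,per_100g
WF020,Biscuits wheat plain brand 20,Grain or grain product,Fine bakery wares,Biscuits,Biscuits,per_100g
WF021,Biscuits wheat plain brand 21,Grain or grain product,Fine bakery wares,Biscuits,Biscuits,per_100g
WF022,Bread rye loaf brand 22,Grain or grain product,Breads,Leavened breads,Bread,per_100g
WF023,Bread wheat wholegrain rusks brand 23,Grain or grain product,Breads,Leavened breads,Bread,per_100g
WF024,Bread wheat wholegrain rusks brand 24,Grain or grain product,Breads,Leavened breads,Bread,per_100g
WF025,Margarine sunflower spreadable unsalted brand 25,Fat or fat product,Vegetable fats,Margarines,Margarine,per_100g
WF026,Margarine sunflower spreadable unsalted brand 26,Fat or fat product,Vegetable fats,Margarines,Margarine,per_100g
WF027,Margarine sunflower spreadable unsalted brand 27,Fat or fat product,Vegetable fats,Margarines,Margarine,per_100g
WF028,Butter cow solid salted brand 28,Fat or fat product,Animal fats,Butters,Butter,per_100g
WF029,Spinach frozen brand 29,Vegetable or vegetable product,Frozen vegetables,Frozen leaf vegetables,Spinach,per_100g
WF030,Spinach frozen brand 30,Vegetable or vegetable product,Frozen vegetables,Frozen leaf vegetables,Spinach,per_100g
WF031,Spinach frozen brand 31,Vegetable or vegetable product,Frozen vegetables,Frozen leaf vegetables,Spinach,per_100g
WF032,Asparagus canned in brine brand 32,Vegetable or vegetable product,Canned vegetables,Canned stem vegetables,Asparagus,per_100g
WF033,Asparagus canned in brine brand 33,Vegetable or vegetable product,Canned vegetables,Canned stem vegetables,Asparagus,per_100g
WF034,Asparagus canned in water brand 34,Vegetable or vegetable product,Canned vegetables,Canned stem vegetables,Asparagus,per_100g
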