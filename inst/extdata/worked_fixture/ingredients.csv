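product_id,ingredients_text
WF001,"milk, lactic cultures"
WF002,"milk, lactic cultures"
WF003,"milk, lactic cultures"
WF004,"milk, lactic cultures"
WF005,"milk, cocoa, sugar"
WF006,"milk, cocoa, sugar"
WF007,"milk, cocoa, sugar"
WF008,"milk, cocoa, sweeteners (stevia)"
WF009,"milk, cocoa, sweeteners (stevia)"
WF010,"milk, cocoa, sweeteners (stevia)"
WF011,"milk, lactic cultures"
WF012,"milk, lactic cultures"
WF013,"milk, lactic cultures"
WF014,"flour, water, yeast, salt"
WF015,"flour, water, yeast, salt"
WF016,"flour, water, yeast, salt"
WF017,"flour, water, yeast, salt"
WF018,"flour, water, yeast, salt"
WF019,"flour, vegetable fat, raising agents"
WF020,"flour, vegetable fat, raising agents"
WF021,"flour, vegetable fat, raising agents"
WF022,"rye flour, water, yeast, salt"
WF023,"flour, water, yeast, salt"
WF024,"flour, water, yeast, salt"
WF025,"vegetable oils, water, emulsifier"
WF026,"vegetable oils, water, emulsifier"
WF027,"vegetable oils, water, emulsifier"
WF028,cream
WF029,spinach
WF030,spinach
WF031,spinach
WF032,asparagus
WF033,asparagus
WF034,asparagus
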