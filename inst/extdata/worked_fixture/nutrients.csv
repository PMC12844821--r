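product_id,energy,protein,total_fat,sfa,carbohydrate,total_sugars,fiber,polyols,sodium
WF001,57.8,10,0.2,0.1,4,4,0,0,50
WF002,58.99999999999999,10.2,0.2,0.1,4.1,4.1,0,0,52
WF003,56.6,9.8,0.2,0.1,3.9,3.9,0,0,48
WF004,57.8,10,0.2,0.1,4,4,0,0,50
WF005,96.7,3.3,3.5,2.2,13,12,0,0,45
WF006,100,3.4,3.6,2.3,13.5,12.5,0,0,46
WF007,93.39999999999999,3.2,3.4,2.1,12.5,11.5,0,0,44
WF008,64.7,3.3,3.5,2.2,5,4,0,0,45
WF009,66.8,3.4,3.6,2.3,5.2,4.2,0,0,46
WF010,62.599999999999994,3.2,3.4,2.1,4.8,3.8,0,0,44
WF011,94,5.5,6,4,4.5,4.5,0,0,55
WF012,73.3,4,4.5,3,4.2,4.2,0,0,50
WF013,73.19999999999999,4.1,4.4,2.9,4.3,4.3,0,0,52
WF014,260,9,4,1.2,45,3.6,4,0,450
WF015,265.9,9.2,4.1,1.2,46,3.7,4.1,0,455
WF016,254.1,8.8,3.9,1.2,44,3.5,3.9,0,445
WF017,262.4,9.1,4,1.2,45.5,3.6,4,0,450
WF018,257.6,8.9,4,1.2,44.5,3.6,4,0,450
WF019,444,7,18,9,62,10,3,0,350
WF020,449.79999999999995,7,18.2,9,63,25,3,0,350
WF021,438.20000000000005,7,17.8,9,61,40,3,0,350
WF022,254,8,2,0.4,48,3,6,0,430
WF023,339,11,5,1.5,60,5,5,0,500
WF024,344.7,11.2,5.1,1.5,61,5.2,5,0,505
WF025,542.8,0.2,60,15,0.5,0.2,0,0,30
WF026,551.8,0.2,61,15.2,0.5,0.2,0,0,31
WF027,533.8,0.2,59,14.8,0.5,0.2,0,0,29
WF028,743.2,0.6,82,52,0.7,0.7,0,0,600
WF029,26.800000000000004,2.9,0.4,0.1,1.8,0.7,2.2,0,80
WF030,27.6,3,0.4,0.1,1.9,0.8,2.2,0,82
WF031,26,2.8,0.4,0.1,1.7,0.6,2.2,0,78
WF032,27.7,2,0.3,0.1,3.5,1.8,1.5,0,350
WF033,28.5,2.1,0.3,0.1,3.6,1.9,1.5,0,355
WF034,27.1,2,0.3,0.1,3.4,1.7,1.4,0,30
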