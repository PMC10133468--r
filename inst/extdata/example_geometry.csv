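subject_id,contact_index,insertion_depth_mm,cdl_mm
EX01,1,20.8281510682139,37.3253705795676
EX01,2,19.8781510682139,37.3253705795676
EX01,3,18.9281510682139,37.3253705795676
EX01,4,17.9781510682139,37.3253705795676
EX01,5,17.0281510682139,37.3253705795676
EX01,6,16.0781510682139,37.3253705795676
EX01,7,15.1281510682139,37.3253705795676
EX01,8,14.1781510682139,37.3253705795676
EX01,9,13.2281510682139,37.3253705795676
EX01,10,12.2781510682139,37.3253705795676
EX01,11,11.3281510682139,37.3253705795676
EX01,12,10.3781510682139,37.3253705795676
EX01,13,9.4281510682139,37.3253705795676
EX01,14,8.4781510682139,37.3253705795676
EX01,15,7.5281510682139,37.3253705795676
EX01,16,6.5781510682139,37.3253705795676
EX02,1,19.33481257903,38.5709300066332
EX02,2,18.38481257903,38.5709300066332
EX02,3,17.43481257903,38.5709300066332
EX02,4,16.48481257903,38.5709300066332
EX02,5,15.53481257903,38.5709300066332
EX02,6,14.58481257903,38.5709300066332
EX02,7,13.63481257903,38.5709300066332
EX02,8,12.68481257903,38.5709300066332
EX02,9,11.73481257903,38.5709300066332
EX02,10,10.78481257903,38.5709300066332
EX02,11,9.83481257902998,38.5709300066332
EX02,12,8.88481257902998,38.5709300066332
EX02,13,7.93481257902998,38.5709300066332
EX02,14,6.98481257902998,38.5709300066332
EX02,15,6.03481257902998,38.5709300066332
EX02,16,5.08481257902998,38.5709300066332
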