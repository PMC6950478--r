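account,commodity,activity,labor,capital,household,government,saving_investment
commodity,0,34632,0,0,6203,4452,7410
activity,52697,0,0,0,0,0,0
labor,0,9117,0,0,0,0,0
capital,0,5987,0,0,0,0,0
household,0,0,9117,5987,0,0,0
government,0,2961,0,0,1490,0,0
saving_investment,0,0,0,0,7410,0,0
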