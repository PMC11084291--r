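name,Rp,Rd,C
right_coronary,5.42e8,7.17e9,2.12e-10
left_coronary,5.42e8,7.17e9,2.12e-10
right_subclavian,7.79e7,1.03e9,1.47e-9
right_common_carotid,7.38e7,9.76e8,1.55e-9
left_common_carotid,1.21e8,1.61e9,9.45e-10
left_subclavian,1.06e8,1.41e9,1.08e-9
descending_aorta,2.01e7,2.66e8,5.70e-9
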