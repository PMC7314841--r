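# room-temperature THz absorption peaks of pressed pellets, 0.2-3.0 THz
# units: frequency in THz, absorption level in cm^-1
form	frequency_thz	absorption_cm
C	1.60	9.75
C	2.76	93.56
C-MH	2.18	24.86
C-MH	2.46	10.74
C-MH	2.76	29.83
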