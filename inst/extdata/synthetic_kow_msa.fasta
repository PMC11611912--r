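>EFP_ECOLI synthetic scaffold carrying documented loop region
KVAKVAKVAKVAKVAKVAKVAKVAKVAKVAKVAKVAKVAK-P-G-K-G-Q-AGEGEGEGE
>EFPL_ECOLI synthetic scaffold carrying documented loop region
KVAKVAKVAKVAKVAKVAKVAKVAKVAKVAKVAKVAKVA--SPTARGAAT--GEGEGEGE
>EFP_RTIP synthetic scaffold carrying documented loop region
KVAKVAKVAKVAKVAKVAKVAKVAKVAKVAKVAKVAKVAK-P-G-R-G-Q-AGEGEGEGE
>KOW_LONG_KTIP synthetic scaffold carrying documented loop region
KVAKVAKVAKVAKVAKVAKVAKVAKVAKVAKVAKVAKVA--SPTAKGAAT--GEGEGEGE
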