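>ANK01 synthetic seed unit
DKDGNTPLHLAASNGHLEIVEVLLKAGADVNAK
>ANK02 synthetic seed unit
DVNGRTPLHLAATNGHLEIVEVLLKNGADVNAK
>ANK03 synthetic seed unit
DLNGQTPLHIAAYKGHLEIVKLLLEHGADVNAK
>ANK04 synthetic seed unit
DEDGYTPLHLAAENGHLEVVKYLVSKGADVNAL
>ANK05 synthetic seed unit
DKNGRTALHYAARSGHLDVVKFLIENGADVNIK
>ANK06 synthetic seed unit
DSDGNTPLHLAVKNNHLSIVQLLLDRGADVNSK
>ANK07 synthetic seed unit
DNKGETPLHVAAFWGHLEIVELLLNAGADVNLK
>ANK08 synthetic seed unit
DIDGNTPLHWAASRGHLEIVRLLLSRNADVNAQ
>ANK09 synthetic seed unit
NKDGNTALHLAAQEGHLEVVQELLKAGADVNMK
>ANK10 synthetic seed unit
DKDGRTPLDLAASNGHTEIVELLLKYGANVNAK
>ANK11 synthetic seed unit
DRDGNSPLHLAAREGHLKIVEVLVKAEADVNAK
>ANK12 synthetic seed unit
DKDANTPLQLAASEGHLEIVEFLLKAGADINAE
>ANK13 synthetic seed unit
DTDGKTPLHLATSKGHLPIVEVLLKAGAKVNAR
>ANK14 synthetic seed unit
GKDGNTPLHAAASNGHVEIVEVLLANGADVHAK
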