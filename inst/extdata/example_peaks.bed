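chrS1	40103	41129	el_0002	10.0
chrS1	55998	57426	el_0003	9.1
chrS1	148720	149858	el_0007	11.4
chrS1	170000	172000	el_0009	10.6
chrS2	52000	53800	el_0101	9.8
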