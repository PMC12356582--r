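{"tolerance_ppm":5,"ions":[{"mz":82.0651,"label":"C5H8N","source":"curated_standard_ions"},{"mz":94.0651,"label":"recurrent_94.0651","source":"library_recurrence"},{"mz":96.0808,"label":"C6H10N","source":"curated_standard_ions"},{"mz":100.0757,"label":"C5H10NO","source":"curated_standard_ions"},{"mz":106.0651,"label":"C7H8N","source":"curated_standard_ions"},{"mz":108.0808,"label":"C7H10N","source":"curated_standard_ions"},{"mz":118.0651,"label":"C8H8N","source":"curated_standard_ions"},{"mz":120.0808,"label":"recurrent_120.0808","source":"library_recurrence"},{"mz":122.0964,"label":"C8H12N","source":"curated_standard_ions"},{"mz":136.0757,"label":"recurrent_136.0757","source":"library_recurrence"},{"mz":138.0913,"label":"recurrent_138.0913","source":"library_recurrence"},{"mz":140.107,"label":"C8H14NO","source":"curated_standard_ions"},{"mz":142.1226,"label":"C8H16NO","source":"curated_standard_ions"},{"mz":144.1019,"label":"C7H14NO2","source":"curated_standard_ions"},{"mz":150.0913,"label":"C9H12NO","source":"curated_standard_ions"},{"mz":154.0863,"label":"recurrent_154.0863","source":"library_recurrence"},{"mz":156.1019,"label":"recurrent_156.1019","source":"library_recurrence"},{"mz":158.1176,"label":"C8H16NO2","source":"curated_standard_ions"},{"mz":168.1019,"label":"C9H14NO2","source":"curated_standard_ions"},{"mz":170.1176,"label":"C9H16NO2","source":"curated_standard_ions"},{"mz":172.0968,"label":"recurrent_172.0968","source":"library_recurrence"},{"mz":180.1019,"label":"C10H14NO2","source":"curated_standard_ions"},{"mz":184.0968,"label":"C9H14NO3","source":"curated_standard_ions"},{"mz":198.1125,"label":"C10H16NO3","source":"curated_standard_ions"},{"mz":224.1281,"label":"C12H18NO3","source":"curated_standard_ions"},{"mz":254.1387,"label":"C13H20NO4","source":"curated_standard_ions"},{"mz":282.17,"label":"recurrent_282.1700","source":"library_recurrence"},{"mz":298.1649,"label":"recurrent_298.1649","source":"library_recurrence"},{"mz":318.17,"label":"recurrent_318.1700","source":"library_recurrence"},{"mz":334.1649,"label":"recurrent_334.1649","source":"library_recurrence"}]}
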