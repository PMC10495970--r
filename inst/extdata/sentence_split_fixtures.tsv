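The solution was stirred. The mixture was filtered.	The solution was stirred.|The mixture was filtered.
The mixture was heated at 25 °C. The mixture was filtered.	The mixture was heated at 25 °C.|The mixture was filtered.
A single sentence without terminal period	A single sentence without terminal period
The reagent (e.g. EDC) was added. Stirring continued.	The reagent (e.g. EDC) was added.|Stirring continued.
The sample was dried (see Note 3. Appendix) and weighed.	The sample was dried (see Note 3. Appendix) and weighed.
Water was added! The phases were separated.	Water was added!|The phases were separated.
Was the product pure? Yes.	Was the product pure?|Yes.
The residue was dissolved in methanol. 4-Bromoaniline was added.	The residue was dissolved in methanol.|4-Bromoaniline was added.
Approx. five grams were used. The rest was discarded.	Approx. five grams were used.|The rest was discarded.
The yield was 85 per cent. 2 g of product were isolated.	The yield was 85 per cent.|2 g of product were isolated.
The mixture was stirred overnight.	The mixture was stirred overnight.
The oil was distilled at 120 °C. No decomposition was observed.	The oil was distilled at 120 °C.|No decomposition was observed.
Solvent was removed in vacuo. The crude was used directly.	Solvent was removed in vacuo.|The crude was used directly.
A solution of NaOH (1 M. aqueous) was prepared beforehand.	A solution of NaOH (1 M. aqueous) was prepared beforehand.
The product was washed with brine. It was then dried.	The product was washed with brine.|It was then dried.
The flask was cooled to 0 °C. Sodium hydride was added portionwise.	The flask was cooled to 0 °C.|Sodium hydride was added portionwise.
See ref. 12 for details of the apparatus employed here.	See ref. 12 for details of the apparatus employed here.
First sentence here. Second sentence here. Third sentence here.	First sentence here.|Second sentence here.|Third sentence here.
The melting point was 134 degrees. Recrystallization followed.	The melting point was 134 degrees.|Recrystallization followed.
The suspension was sonicated for 5 min. TLC showed completion.	The suspension was sonicated for 5 min.|TLC showed completion.
The reaction was quenched carefully. and the layers were separated.	The reaction was quenched carefully. and the layers were separated.
An aliquot (ca. 0.5 mL) was removed. Analysis confirmed purity.	An aliquot (ca. 0.5 mL) was removed.|Analysis confirmed purity.
Heating continued for 2 h. After cooling, the solid was collected.	Heating continued for 2 h.|After cooling, the solid was collected.
The pH was adjusted to 7.5 with dilute acid before extraction.	The pH was adjusted to 7.5 with dilute acid before extraction.
The title reaction gave a solid. "Purity was excellent." It was stored cold.	The title reaction gave a solid.|"Purity was excellent."|It was stored cold.
No product was observed at rt. 60 °C proved necessary.	No product was observed at rt.|60 °C proved necessary.
The catalyst (Pd, 5 mol%) was added. Hydrogenation began at once.	The catalyst (Pd, 5 mol%) was added.|Hydrogenation began at once.
Concentration gave an oil. Trituration with hexane gave a powder.	Concentration gave an oil.|Trituration with hexane gave a powder.
The ether extract was dried over MgSO4. Filtration and evaporation followed.	The ether extract was dried over MgSO4.|Filtration and evaporation followed.
The vessel was sealed. Microwave heating at 120 °C for 30 min gave full conversion.	The vessel was sealed.|Microwave heating at 120 °C for 30 min gave full conversion.
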