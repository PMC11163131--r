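{
  "dataset": "eye-infection drug benchmark",
  "version": "1.0.0",
  "n_drugs": 20,
  "units": {
    "MW": "g/mol",
    "BP": "degC",
    "EV": "kJ/mol",
    "FP": "degC",
    "MR": "cm3/mol (source table labels this cubic meters per mole)",
    "MV": "cm3/mol (source table labels this cubic meters per mole)"
  },
  "properties": ["MW", "BP", "EV", "FP", "MR", "MV"],
  "comparison_rules": {
    "integer_indices": "M1, M2, F, HM compared exactly",
    "float_indices": "mM2, H, SD, SRR compared at |diff| <= 5e-3 + 10^-d where d is the number of printed decimals (the reference table truncates or loosely rounds at 2 decimals)",
    "FRR": "compared under the as_tabulated variant 1/sqrt(2(ab+a+b)) at 0.5% relative tolerance; the reference column appears to have been summed from per-class terms rounded to 3 decimals. Under the as_stated definition 1/(ab+a+b) the whole column disagrees by construction and the validator annotates this known formula/table discrepancy."
  },
  "structure_notes": {
    "Amoxicillin": "synthetic source-consistent variant, not the true amoxicillin connectivity: the reference row (including SRR 27.267 exactly) is reproduced only by the true graph with the thiazolidine S-C bond removed and one extra terminal atom, evidently how the structure was drawn in the source; the true free base gives M1 138, not the printed 136.",
    "Ciprofloxacin": "true ciprofloxacin free base. The printed reference row is internally inconsistent: exhaustive enumeration shows no graph with maximum degree 4 matches more than 5 of its 9 cells, so the whole row is flagged suspect rather than the structure altered."
  },
  "suspect_cells": {
    "Tetrahydrozoline": ["HM", "FRR", "SRR"],
    "Oxymetazoline": ["FRR", "SRR"],
    "Antazoline": ["SRR"],
    "Ciprofloxacin": ["M1", "M2", "mM2", "H", "F", "HM", "SD", "FRR", "SRR"],
    "Moxifloxacin": ["FRR"],
    "Tobramycin": ["SD"],
    "Amoxicillin": ["SD"],
    "Dexamethasone": ["FRR", "SRR"],
    "Azithromycin": ["SRR"]
  },
  "suspect_notes": {
    "Tetrahydrozoline": "printed HM 521 violates the HM = F + 2*M2 identity (F 196, M2 95 imply 386); printed FRR/SRR are far from any value consistent with the printed classical indices.",
    "Oxymetazoline": "the unique degree<=4 partition matching the seven classical printed cells yields FRR 4.431 and SRR 19.506, not the printed 3.690/18.005.",
    "Antazoline": "the unique matching partition yields SRR 13.998, not the printed 13.776.",
    "Ciprofloxacin": "no degree<=4 graph reproduces the printed row; the defluorinated structure matches M1, H and HM exactly but not M2/F, indicating several hand-calculation slips.",
    "Moxifloxacin": "printed FRR 6.464 is 10% from the value implied by the partition that reproduces every other cell (7.165 under the as_tabulated variant).",
    "Tobramycin": "printed SD 80 vs 82 from the partition that reproduces SRR 31.449 exactly.",
    "Amoxicillin": "printed SD 71.66 appears to transpose the true 71.17 of the source-consistent partition.",
    "Dexamethasone": "the unique matching partition yields FRR 6.569 and SRR 31.110, not the printed 6.386/29.544.",
    "Azithromycin": "no degree<=4 partition reproduces the printed SRR 52.669 together with the other cells (closest gap 1.4); the structure's value is 58.050."
  }
}
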