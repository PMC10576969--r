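# Independent re-encoding of the packaged registry: for each taxon a string
# of 8 status codes (Y = indicator, N = not, Q = qualified) in body order
# NPFC, SPRFMO, NEAFC, NAFO_ABNJ, CCAMLR, SEAFO, GFCM, SIOFA.
EXPECTED_CELLS <- c(
  Actiniaria           = "NYNNYNNY",
  Ceriantharia         = "NNQQNQYN",
  Alcyonacea           = "QQYQQQYQ",
  Pennatulacea         = "NYYYYYYY",
  Antipatharia         = "YYQYYYYY",
  Scleractinia         = "YQYQYYYY",
  Hydroidolina         = "NQNNYQYQ",
  Stylasteridae        = "NYYNYNQY",
  Zoantharia           = "NYNNYYNY",
  Brisingida           = "NYNNNNNN",
  Crinoidea            = "NYQQQYYQ",
  Echinoidea           = "NNNNQNNQ",
  Ophiuroidea          = "NNNNQQNQ",
  Arthropoda           = "NNQNQNNQ",
  Ascidiacea           = "NNNYYYNY",
  Bivalvia             = "NNQNQNQN",
  Brachiopoda          = "NNNNYNNY",
  Bryozoa              = "NQQQYYQY",
  Polychaeta           = "NNQNQQQQ",
  Porifera             = "NQYYQYQQ",
  Pterobranchia        = "NNNNYNNY",
  Xenophyophoroidea    = "NNYYYNNY",
  `Chemosynthetic taxa` = "NNQNYNYY",
  `Seamounts as a whole` = "NNQYNNQN")
BODY_ORDER <- c("NPFC", "SPRFMO", "NEAFC", "NAFO_ABNJ", "CCAMLR", "SEAFO",
                "GFCM", "SIOFA")

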