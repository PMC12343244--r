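# Shared small fixtures built in code.

tinyVocab <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- buildMotifVocabulary(c("Cc1ccccc1", "CCO", "c1ccncc1",
                                       "CC(C)(C)C"))
    cache
  }
})

tinyModel <- function(..., seed = 0L) {
  args <- utils::modifyList(list(hiddenSize = 8L, depth = 2L,
                                 attnLayers = 1L, headsPerChannel = 2L),
                            list(...))
  motifFuseModel(tinyVocab(), do.call(motifFuseConfig, args), seed = seed)
}

# 30-molecule curated decomposition suite: ring-substituent cleavage,
# branching atoms, fused/spiro bicyclics, heteroaromatics, and the biaryl
# amide from the attention case study (both readings of its trailing
# methyl).
curatedSuite <- function() c(
  "Cc1ccccc1",                      # toluene
  "CC(C)(C)C",                      # neopentane
  "C1CC1",                          # cyclopropane
  "c1ccccc1",                       # benzene
  "C1CCCCC1",                       # cyclohexane
  "c1ccc2ccccc2c1",                 # naphthalene (fused, intact)
  "C1Cc2ccccc2C1",                  # indane
  "C1CCC2CCCCC2C1",                 # decalin
  "C1CCC2(CC1)CCCC2",               # spiro[5.4]decane
  "c1ccc(-c2ccccc2)cc1",            # biphenyl
  "c1ccncc1",                       # pyridine
  "Nc1ccccc1",                      # aniline
  "OC(=O)c1ccccc1",                 # benzoic acid
  "CC(C)(C)c1ccccc1",               # tert-butylbenzene
  "CC(=O)O",                        # acetic acid (branch atom)
  "CC(C)=O",                        # acetone (branch atom)
  "CCN(CC)CC",                      # triethylamine (branch atom)
  "OCC(O)CO",                       # glycerol (branch atom)
  "CC(C)O",                         # isopropanol (branch atom)
  "C=Cc1ccccc1",                    # styrene
  "Clc1ccccc1Cl",                   # dichlorobenzene
  "c1ccc2ncccc2c1",                 # quinoline
  "CCOC(=O)c1ccc(N)cc1",            # benzocaine-like ester
  "CC1CCCCC1",                      # methylcyclohexane
  "CCO",                            # ethanol (acyclic chain)
  "CCCCCC",                         # hexane (acyclic chain)
  "CNC(=O)c1ccccc1",                # benzamide
  "Cc1ccc(cc1)S(=O)(=O)N",          # tosylamide-like
  "O=C(NCc1cccnc1)C(Cc1cc2cc(ccc2nc1N)-c1ccccc1C)C",
  "O=C(NCc1cccnc1)C(Cc1cc2cc(ccc2nc1N)-c1ccccc1C)"
)
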