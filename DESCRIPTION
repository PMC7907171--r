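Package: evoreliab
Title: Semantic Reliability of Evolved Controllers and Parsimony-Pressure Neuroevolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Two evolutionary experiments and the exhaustive semantic-equivalence
    machinery to compare their products. A tree-based genetic programming engine
    evolves boolean control programs for a wall-following robot in a 2D grid
    labyrinth; a neuroevolution engine evolves populations of trained
    one-hidden-layer networks under a size-penalized fitness F = Q - lambda*sigma
    toward minimal AND/XOR implementations. A parser and evaluator for the
    boolean program dialect (If[.,.,.], &&, ||, !, True, False over twelve named
    variables) enumerate all 4,096 input states, so that champion programs that
    behave identically inside the labyrinth can be compared as boolean functions
    and their pairwise disagreement counted.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    rlang,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
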