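# Fixture networks built in code; all small enough for brute-force oracles.

quartet_tree <- function() {
  phynet(rbind(c("a", "u"), c("b", "u"), c("u", "v"), c("c", "v"), c("d", "v")))
}

star3 <- function() {
  phynet(rbind(c("a", "u"), c("b", "u"), c("c", "u")))
}

# two triangles joined by a bridge, pendant leaves to make degrees valid
two_blob_net <- function() {
  phynet(rbind(
    c("u1", "u2"), c("u2", "u3"), c("u1", "u3"),
    c("w1", "w2"), c("w2", "w3"), c("w1", "w3"),
    c("u1", "w1"),
    c("a", "u2"), c("b", "u3"), c("c", "w2"), c("d", "w3")))
}

# K4 with one edge subdivided once and a single pendant leaf: improper
# (its only cut-edge has a leafless side)
k4_single_leaf <- function() {
  phynet(rbind(c("a", "s"), c("s", "b"), c("a", "c"), c("a", "d"),
               c("b", "c"), c("b", "d"), c("c", "d"), c("s", "x")))
}

petersen_net <- function() named_fixture("petersen_net")
k4_net <- function() named_fixture("k4_net")
triangle3 <- function() named_fixture("triangle3")
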