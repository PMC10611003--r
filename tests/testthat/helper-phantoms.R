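# Table-1 phantom parameters (d mm, mus' 1/mm, mua 1/mm), built in code so
# tests do not depend on the bundled fixture file.
TABLE1 <- list(
  "1.1" = c(d = 0.395, mus_prime = 3.688, mua = 0.0034),
  "1.2" = c(d = 0.947, mus_prime = 3.781, mua = 0.0020),
  "1.3" = c(d = 1.514, mus_prime = 3.841, mua = 0.0020),
  "1.4" = c(d = 1.987, mus_prime = 3.817, mua = 0.0019),
  "2.1" = c(d = 0.901, mus_prime = 2.724, mua = 0.0213),
  "2.2" = c(d = 1.045, mus_prime = 2.757, mua = 0.0598)
)

table1_slab <- function(id, g = 0.6) {
  p <- TABLE1[[id]]
  optical_slab(d = p[["d"]], mus_prime = p[["mus_prime"]],
               mua = p[["mua"]], g = g, id = id)
}
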