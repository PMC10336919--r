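# Shared fixtures, built once per test run.

.fixture_env <- new.env()

# 100-molecule grammar library with 20 planted coumarin cores
fixture_library <- function() {
  if (is.null(.fixture_env$lib))
    .fixture_env$lib <- ms_generate_library(
      ms_fixture_spec(100, seed = 42, coumarin_fraction = 0.2,
                      nitrogen_fraction = 0.5, nitro_fraction = 0.25))
  .fixture_env$lib
}

fixture_project <- function() {
  if (is.null(.fixture_env$proj)) {
    lib <- fixture_library()
    p <- ms_project("fixture")
    for (i in seq_len(nrow(lib)))
      p <- ms_add_molecule(p, lib$id[i], lib$smiles[i])
    .fixture_env$proj <- p
  }
  .fixture_env$proj
}

# three-molecule toy set for the multi-condition property-query example
toy_query_project <- function() {
  p <- ms_project("toy")
  p <- ms_add_molecule(p, "A", "CCO",
                       list(MW = "350.2", LogP = "1.5", Formula = "C20H18N2O3"))
  p <- ms_add_molecule(p, "B", "CCN",
                       list(MW = "250.0", LogP = "1.0", Formula = "C15H14O4"))
  ms_add_molecule(p, "C", "CCC",
                  list(MW = "410.5", LogP = "3.2", Formula = "C25H22N2O2"))
}

# constant-probability stand-in classifier, for exercising the consensus
# arithmetic without a trained forest
const_model <- function(p) structure(list(p = p), class = "const_model")
predict.const_model <- function(object, newdata, type = "prob", ...) {
  matrix(c(1 - object$p, object$p), nrow = nrow(newdata), ncol = 2,
         byrow = TRUE, dimnames = list(NULL, c("0", "1")))
}
.S3method("predict", "const_model", predict.const_model)

const_ensemble <- function(probs) {
  structure(list(models = lapply(probs, const_model),
                 keep_cols = seq_len(16),
                 meta = list(seed = 0, n_models = length(probs))),
            class = "molstash_ensemble")
}
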