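.onLoad <- function(libname, pkgname) {
  # Small recurrent GEMMs are slower and noisier under a threaded BLAS;
  # single-threading also makes training runs bit-reproducible.
  try(set_blas_threads(1L), silent = TRUE)
  invisible()
}
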