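.onLoad <- function(libname, pkgname) {
  # small GEMMs: thread spin-up costs more than it saves
  tryCatch(blas_single_thread_cpp(), error = function(e) NULL)
  invisible(NULL)
}
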