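# The model's matrix algebra is dominated by many small matrix products;
# multi-threaded BLAS synchronisation costs more than the arithmetic there,
# so pin BLAS/OpenMP to one thread unless the user configured it already.
.onLoad <- function(libname, pkgname) {
  for (v in c("OPENBLAS_NUM_THREADS", "OMP_NUM_THREADS",
              "GOTO_NUM_THREADS", "MKL_NUM_THREADS")) {
    if (!nzchar(Sys.getenv(v))) {
      args <- list("1")
      names(args) <- v
      do.call(Sys.setenv, args)
    }
  }
}
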