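#' @importFrom data.table := .SD data.table as.data.table rbindlist
#' @importFrom stats rnorm runif rgamma rexp rpois plogis qt sd var median anova
NULL

.datatable.aware <- TRUE

# quiet R CMD check notes for data.table NSE columns
utils::globalVariables(c("participant_id", "valid", "aoi", ".", "..keys"))
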