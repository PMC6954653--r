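#' @keywords internal
#' @noRd
iscn_stop <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "iscn_error"), call = call))
}

# condition classes used throughout:
#   iscn_parse_error        malformed designation text
#   iscn_unsupported_error  legal ISCN outside the supported dialect
#   iscn_structure_error    arity / shape violation inside an event
#   iscn_validation_error   reference to a nonexistent chromosome or band
#   iscn_consistency_error  declared vs computed total mismatch
#   iscn_format_error       band-table violations at load time
#   iscn_lookup_error       unknown band / class / backend name
#   iscn_domain_error       operation outside its domain (e.g. cross-chromosome)
#   iscn_resolution_error   band not visible nor expandable at a resolution
#   iscn_capability_error   backend does not support the operation
#   iscn_config_error       invalid generator / fixture configuration
#   iscn_usage_error        bad command-line invocation
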