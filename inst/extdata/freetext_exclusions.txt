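# Free-text strings that match the otitis search patterns ("oti*", "*oti*",
# "om*", "*om*") but are not acute otitis media. Stands in for manual
# clinical review of free-text matches; one exact normalized string per line.
vomito
vomito e diarrea
dolore addominale
vomito e febbre
addome trattabile
insonnia e vomito
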