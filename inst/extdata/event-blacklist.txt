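# Uninformative adverse-event terms excluded from signal detection.
# One term per line; matching is case-insensitive; lines starting with '#'
# are comments. Edit freely.
drug ineffective
product quality issue
off label use
drug dose omission
medication error
condition aggravated
no adverse event
therapeutic response unexpected
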