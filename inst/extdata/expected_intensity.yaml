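# Expected treatment-intensity range per Cobb band: the modal personalised
# options for each clinical situation. Editable; adherence-outside-range
# figures depend entirely on this configuration.
"11-20": [0, 1]
"21-30": [1, 2, 3]
"31-40": [4, 5, 6]
"41-45": [6]
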