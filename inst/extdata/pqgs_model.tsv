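# copyNumber=18
name	autonomous	carriesMarker	perCopyCost
ancestral	TRUE	TRUE	0.0306
satellite	FALSE	FALSE	0
deletion	TRUE	TRUE	0.0050
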