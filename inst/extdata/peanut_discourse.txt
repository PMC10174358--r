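The Peanut. A woman saw a dancing peanut who had a big smile on his face.
The peanut was singing about a girl he had just met. And judging from the
song the peanut was totally crazy about her. The woman thought it was
really cute to see the peanut singing and dancing like that. The peanut
was salted/in love and by the sound of it this was definitely mutual. He
was seeing a little almond.
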