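category,count
total_workers,866
service_delivery,489
administrative,377
nurses,220
physicians,176
health_promoters,39
allied_professionals,15
dentists_and_students,39
attended_urban,233618
attended_rural,34909
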