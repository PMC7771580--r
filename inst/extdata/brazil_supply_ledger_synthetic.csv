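date,region,quantity,unit
2013-02-01,BR,413.87,metric_tons
2013-03-01,BR,413.87,metric_tons
2013-04-01,BR,413.87,metric_tons
2013-05-01,BR,413.87,metric_tons
2013-06-01,BR,413.87,metric_tons
2013-07-01,BR,413.87,metric_tons
2013-08-01,BR,413.87,metric_tons
2013-09-01,BR,413.87,metric_tons
2013-10-01,BR,413.87,metric_tons
2013-11-01,BR,413.87,metric_tons
2013-12-01,BR,413.87,metric_tons
2014-01-01,BR,413.87,metric_tons
2014-02-01,BR,413.87,metric_tons
2014-03-01,BR,413.87,metric_tons
2014-04-01,BR,413.87,metric_tons
2014-05-01,BR,413.87,metric_tons
2014-06-01,BR,413.87,metric_tons
2014-07-01,BR,413.87,metric_tons
2014-08-01,BR,413.87,metric_tons
2014-09-01,BR,413.87,metric_tons
2014-10-01,BR,413.87,metric_tons
2014-11-01,BR,413.87,metric_tons
2014-12-01,BR,413.87,metric_tons
2015-01-01,BR,413.87,metric_tons
2015-02-01,BR,413.87,metric_tons
2015-03-01,BR,413.87,metric_tons
2015-04-01,BR,413.94,metric_tons
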